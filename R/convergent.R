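#' Build a fixed 16-dimensional word-embedding table
#'
#' The convergent circuit's correct-answer signal represents each vocabulary
#' word (and UNK) as a unique point in a low-dimensional space, fixed
#' throughout training. Three sources are supported:
#' \describe{
#'   \item{`"synthetic-cooccurrence"`}{truncated SVD of the log
#'     co-occurrence matrix of a (training) corpus, so words sharing contexts
#'     get nearby rows -- a self-contained analogue of reduced pretrained
#'     vectors.}
#'   \item{`"random"`}{seeded Gaussian rows.}
#'   \item{`"pretrained-reduced"`}{rows read from a whitespace word-vector
#'     text file (word followed by floats) and reduced to `n_dim` principal
#'     components; words missing from the file fall back to seeded random
#'     rows (count reported via a warning).}
#' }
#' Duplicate or all-zero rows are perturbed by a tiny seeded jitter so every
#' word has a distinct pattern.
#'
#' @param vocab A `cann_vocabulary`.
#' @param corpus Encoded corpus (required for `"synthetic-cooccurrence"`).
#' @param source Embedding source (see above).
#' @param n_dim Embedding dimensionality (default 16).
#' @param seed Integer seed.
#' @param vectors_path Path to a word-vector text file (for
#'   `"pretrained-reduced"`).
#' @param window Co-occurrence window half-width in tokens (default 2).
#' @return A `(V+1) x n_dim` numeric matrix of class `cann_embedding` with the
#'   source recorded as an attribute; row `V+1` is the UNK cell.
#' @export
build_embedding <- function(vocab,
                            corpus = NULL,
                            source = c("synthetic-cooccurrence", "random",
                                       "pretrained-reduced"),
                            n_dim = 16L, seed = 1L,
                            vectors_path = NULL, window = 2L) {
  source <- match.arg(source)
  n <- vocab$unk_index
  n_dim <- as.integer(n_dim)
  emb <- switch(
    source,
    "random" = with_seed(seed, matrix(stats::rnorm(n * n_dim), n, n_dim)),
    "synthetic-cooccurrence" = {
      if (is.null(corpus) || is.null(corpus$code)) {
        abort("`corpus` with codes is required for the co-occurrence source.")
      }
      cooc <- matrix(0, n, n)
      for (codes in sentence_list(corpus)) {
        t_len <- length(codes)
        for (t in seq_len(t_len)) {
          lo <- max(1L, t - window); hi <- min(t_len, t + window)
          for (u in setdiff(lo:hi, t)) {
            cooc[codes[t], codes[u]] <- cooc[codes[t], codes[u]] + 1
          }
        }
      }
      m <- log1p(cooc)
      sv <- svd(m, nu = n_dim, nv = 0)
      e <- sv$u %*% diag(sqrt(sv$d[seq_len(n_dim)]), n_dim)
      scale(e, center = TRUE, scale = FALSE)
    },
    "pretrained-reduced" = {
      if (is.null(vectors_path)) {
        abort("`vectors_path` is required for the pretrained-reduced source.")
      }
      vecs <- read_word_vectors(vectors_path)
      dims <- ncol(vecs)
      e <- matrix(NA_real_, n, dims)
      hit <- match(vocab$words, rownames(vecs))
      e[seq_along(vocab$words), ] <- vecs[hit, ]
      missing_n <- sum(is.na(hit)) + 1L  # UNK never has a pretrained vector
      e[is.na(e[, 1]), ] <- with_seed(
        derive_seed(seed, 7L),
        matrix(stats::rnorm(missing_n * dims), missing_n, dims))
      if (missing_n > 1L) {
        warn(sprintf("%d in-vocabulary words missing from '%s'; random rows used.",
                     missing_n - 1L, vectors_path))
      }
      pc <- stats::prcomp(e, center = TRUE, scale. = FALSE)
      pc$x[, seq_len(n_dim), drop = FALSE]
    })
  # overall unit scale keeps squared-error magnitudes comparable across sources
  s <- stats::sd(emb)
  if (is.finite(s) && s > 0) emb <- emb / s
  dup <- duplicated(emb) | rowSums(abs(emb)) == 0
  if (any(dup)) {
    jit <- with_seed(derive_seed(seed, 13L),
                     matrix(stats::rnorm(sum(dup) * n_dim, sd = 1e-4),
                            sum(dup), n_dim))
    emb[dup, ] <- emb[dup, ] + jit
  }
  rownames(emb) <- c(vocab$words, "<UNK>")
  structure(emb, class = c("cann_embedding", "matrix", "array"),
            source = source, seed = seed)
}

# Whitespace word-vector text reader: `word v1 v2 ...` per line.
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(mat) <- words
  mat
}

#' Decode a population-coded output into a word
#'
#' The predicted word is the vocabulary cell whose embedding row is closest
#' (Euclidean) to the output-cell activity pattern; ties go to the lowest
#' index.
#'
#' @param output Numeric vector (length `n_dim`).
#' @param embedding A `cann_embedding` table.
#' @return Integer vocabulary cell index.
#' @export
decode_word <- function(output, embedding) {
  d2 <- rowSums(sweep(unclass(embedding), 2, output)^2)
  as.integer(which.min(d2))
}

#' Index of the module closest to the correct-answer signal
#'
#' @param outputs Matrix of module outputs (`n_modules x n_dim`).
#' @param target Embedding row of the actual next word.
#' @return Integer module index (ties to the lowest index).
#' @export
winner_module <- function(outputs, target) {
  d2 <- rowSums(sweep(outputs, 2, target)^2)
  which.min(d2)
}

#' Build a modular ("convergent") circuit bank
#'
#' Arranges `n_modules` copies of the prediction circuit in parallel. Each
#' module is the original three-layer circuit except for having `n_dim`
#' (default 16) output cells, mirroring the anatomical convergence from many
#' Purkinje cells onto few output neurons; all modules share the one-hot
#' input-cell convention (parallel fibres cross modules). The correct-answer
#' signal is the fixed embedding row of the actual next word.
#'
#' @param vocab A `cann_vocabulary`.
#' @param embedding A `cann_embedding` (its width sets the output size).
#' @param n_modules Number of modules (default 10).
#' @param n_purkinje Purkinje cells per module (default 192).
#' @param seed Integer seed (each module gets a derived seed).
#' @param variant Circuit variant used for every module.
#' @return An object of class `cann_bank`.
#' @export
build_module_bank <- function(vocab, embedding, n_modules = 10L,
                              n_purkinje = 192L, seed = 1L,
                              variant = "original") {
  check_scalar_number(n_modules, "n_modules", 1)
  n_dim <- ncol(embedding)
  modules <- lapply(seq_len(n_modules), function(m) {
    build_circuit(n_input = vocab$unk_index, n_purkinje = n_purkinje,
                  n_output = n_dim, variant = variant,
                  seed = derive_seed(seed, m))
  })
  structure(list(modules = modules, embedding = embedding, vocab = vocab,
                 n_modules = as.integer(n_modules), seed = seed,
                 module_scores = NULL),
            class = "cann_bank")
}

#' @export
print.cann_bank <- function(x, ...) {
  cat(sprintf("<cann_bank> %d modules (%d Purkinje cells each, %d output cells), embedding source '%s'\n",
              x$n_modules, x$modules[[1]]$arch$n_purkinje,
              x$modules[[1]]$arch$n_output, attr(x$embedding, "source")))
  invisible(x)
}

# One-step winner gradient: squared-error loss between the winner's n_dim
# output and the target embedding row, incoming recurrent activity treated as
# given. Output activation is linear (alpha = 1).
winner_gradients <- function(module, code, x_rec, target) {
  a <- ff_column(module, code) + drop(module$W_rec %*% x_rec) + module$b_p
  p <- leaky_relu(a, module$alpha$purkinje)
  o <- drop(module$W_out %*% p) + module$b_out
  d_o <- 2 * (o - target) / length(o)         # mean squared error
  d_a <- drop(crossprod(module$W_out, d_o)) *
    leaky_relu_grad(a, module$alpha$purkinje)
  gW_ff <- matrix(0, module$arch$n_purkinje, module$arch$n_input)
  gW_ff[, code] <- d_a
  grads <- list(W_rec = tcrossprod(d_a, x_rec), b_p = d_a,
                W_out = tcrossprod(d_o, p), b_out = d_o)
  if (module$variant == "ei-split-input") {
    grads$W_exc <- gW_ff; grads$W_inh <- gW_ff
  } else {
    grads$W_ff <- gW_ff
  }
  grads[intersect(trainable_fields(module), names(grads))]
}

#' Train a convergent circuit bank with winner-take-error gating
#'
#' Words are presented sequentially; at every prediction position all modules
#' run forward (each advancing its own recurrent state), and only the module
#' whose output is closest to the correct-answer embedding receives the
#' squared-error gradient step -- all other modules are untouched at that
#' step. Per-module selection counts and exact-decoding accuracies over the
#' final eighth of the last lap are recorded for module ranking.
#'
#' @param bank A `cann_bank`.
#' @param split A `corpus_split` of encoded sentences.
#' @param config A [train_config()] (its `learning_rate`, `epochs` and `seed`
#'   are used; updates are per prediction position).
#' @param audit If `TRUE`, record after every update step how many modules'
#'   parameters changed (via per-module weight digests) and which module won,
#'   so gating exclusivity can be verified.
#' @return An object of class `cann_convergent_fit`: the trained `bank` (with
#'   `module_scores` filled in), a per-epoch `log` tibble with validation
#'   top-k rate over all modules, `selection_counts`, and (when requested)
#'   an `audit` tibble.
#' @export
train_convergent <- function(bank, split,
                             config = train_config(learning_rate = 0.05),
                             audit = FALSE) {
  stopifnot(inherits(bank, "cann_bank"), inherits(split, "corpus_split"))
  emb <- unclass(bank$embedding)
  train_codes <- sentence_list(split$train)
  train_codes <- train_codes[lengths(train_codes) >= 2L]
  val_codes <- sentence_list(split$validation)
  n_train <- length(train_codes)
  n_mod <- bank$n_modules
  selection <- integer(n_mod)
  log_rows <- list()
  final_correct <- integer(n_mod); final_total <- 0L
  module_digest <- function(m) {
    sum(abs(m$b_p)) + sum(abs(m$b_out)) + sum(abs(m$W_out[, 1L]))
  }
  digests <- if (audit) vapply(bank$modules, module_digest, numeric(1))
  audit_rows <- if (audit) {
    list(step = integer(0), winner = integer(0), n_changed = integer(0),
         winner_changed = logical(0))
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_train)
      last_stretch_start <- if (epoch == config$epochs) {
        ceiling(n_train * 7 / 8)
      } else {
        Inf
      }
      for (si in seq_along(ord)) {
        codes <- train_codes[[ord[si]]]
        in_stretch <- si > last_stretch_start
        bank$modules <- lapply(bank$modules, reset_state)
        t_n <- length(codes) - 1L
        for (t in seq_len(t_n)) {
          target <- emb[codes[t + 1L], ]
          outputs <- matrix(0, n_mod, ncol(emb))
          xrec_in <- vector("list", n_mod)
          for (m in seq_len(n_mod)) {
            xrec_in[[m]] <- bank$modules[[m]]$recurrent_activity
            step <- forward_step(bank$modules[[m]], codes[t])
            bank$modules[[m]] <- step$circuit
            outputs[m, ] <- step$output
          }
          w <- winner_module(outputs, target)
          selection[w] <- selection[w] + 1L
          if (in_stretch) {
            final_total <- final_total + 1L
            for (m in seq_len(n_mod)) {
              if (decode_word(outputs[m, ], bank$embedding) == codes[t + 1L]) {
                final_correct[m] <- final_correct[m] + 1L
              }
            }
          }
          g <- winner_gradients(bank$modules[[w]], codes[t], xrec_in[[w]],
                                target)
          bank$modules[[w]] <- apply_update(bank$modules[[w]], g,
                                            config$learning_rate)
          if (audit) {
            new_digests <- vapply(bank$modules, module_digest, numeric(1))
            k <- length(audit_rows$step) + 1L
            audit_rows$step[k] <- k
            audit_rows$winner[k] <- w
            audit_rows$n_changed[k] <- sum(new_digests != digests)
            audit_rows$winner_changed[k] <- new_digests[w] != digests[w]
            digests <- new_digests
          }
          if (!all(is.finite(bank$modules[[w]]$W_out))) {
            abort(sprintf("Convergent training diverged at epoch %d, sentence %d.",
                          epoch, si))
          }
        }
      }
      ev <- evaluate_bank(bank, val_codes, k = min(config$top_k, n_mod))
      log_rows[[epoch]] <- tibble(epoch = epoch, fraction_of_lap = 1,
                                  val_top5_rate_all = ev$rate_all,
                                  seed = config$seed)
    }
  })
  bank$module_scores <- tibble(
    module = seq_len(n_mod),
    final_stretch_accuracy = if (final_total) 100 * final_correct / final_total
    else NA_real_,
    selection_count = selection)
  structure(list(bank = bank, log = dplyr::bind_rows(log_rows),
                 selection_counts = selection, config = config,
                 audit = if (audit) as_tibble(audit_rows)),
            class = "cann_convergent_fit")
}

# Top-k correct rate of a bank on validation sentences using all modules'
# decoded words as the candidate set (UNK targets excluded).
evaluate_bank <- function(bank, code_list, modules = seq_len(bank$n_modules),
                          k = length(modules)) {
  emb <- bank$embedding
  unk <- bank$vocab$unk_index
  hits <- 0L; elig <- 0L
  for (codes in code_list) {
    t_n <- length(codes) - 1L
    if (t_n < 1L) next
    mods <- lapply(bank$modules[modules], reset_state)
    for (t in seq_len(t_n)) {
      words <- integer(length(mods))
      for (m in seq_along(mods)) {
        step <- forward_step(mods[[m]], codes[t])
        mods[[m]] <- step$circuit
        words[m] <- decode_word(step$output, emb)
      }
      j <- codes[t + 1L]
      if (j != unk) {
        elig <- elig + 1L
        if (j %in% words) hits <- hits + 1L
      }
    }
  }
  list(rate_all = if (elig) 100 * hits / elig else NA_real_, eligible = elig)
}

#' Select the best-performing modules
#'
#' Ranks modules by their exact-decoding accuracy over the final eighth of
#' the last training lap and returns the indices of the top `k` (ties to the
#' lower index). The bank's top-k candidate set at a position is the decoded
#' words of the selected modules.
#'
#' @param fit A `cann_convergent_fit` (or a `cann_bank` with
#'   `module_scores`).
#' @param k Number of modules to select (default 5).
#' @return Integer vector of module indices, best first.
#' @export
rank_and_select_modules <- function(fit, k = 5L) {
  bank <- if (inherits(fit, "cann_convergent_fit")) fit$bank else fit
  scores <- bank$module_scores
  if (is.null(scores)) abort("No module scores: train the bank first.")
  if (k > nrow(scores)) {
    abort(sprintf("`k` (%d) exceeds the module count (%d).",
                  as.integer(k), nrow(scores)))
  }
  ord <- order(-scores$final_stretch_accuracy, scores$module)
  scores$module[ord][seq_len(k)]
}

#' Correct rate of a convergent bank's top-k module predictions
#'
#' @param fit A `cann_convergent_fit`.
#' @param corpus Encoded evaluation corpus.
#' @param k Number of top-ranked modules whose decoded words form the
#'   candidate set (default 5).
#' @return Percentage of non-UNK prediction positions whose target is among
#'   the candidates.
#' @export
correct_rate_convergent <- function(fit, corpus, k = 5L) {
  sel <- rank_and_select_modules(fit, k)
  ev <- evaluate_bank(fit$bank, sentence_list(corpus), modules = sel, k = k)
  if (!ev$eligible) abort("No eligible prediction positions (all targets UNK).")
  ev$rate_all
}
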