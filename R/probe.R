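#' Top-k prediction candidates
#'
#' The candidate words for the next word are the `k` output cells with the
#' strongest activity, in descending order; ties go to the lower cell index.
#'
#' @param output Output-layer activity vector.
#' @param k Number of candidates (default 5).
#' @return Integer vector of `k` cell indices.
#' @export
topk_candidates <- function(output, k = 5L) {
  k <- as.integer(k)
  if (k < 1L || k > length(output)) {
    abort(sprintf("`k` must be in 1..%d.", length(output)))
  }
  order(-output, seq_along(output))[seq_len(k)]
}

# Resolve any supported model object to a plain circuit.
as_circuit <- function(model) {
  if (inherits(model, "cann_fit")) model$circuit
  else if (inherits(model, "cann_circuit")) model
  else abort("`model` must be a cann_circuit or cann_fit.")
}

#' Top-k correct prediction rate
#'
#' Scores next-word predictions over all prediction positions of an encoded
#' corpus: a position is a hit when the actual next word is among the top-k
#' candidates. Positions whose target is the UNK cell are excluded from both
#' numerator and denominator (a correct "unknown" is not a prediction of a
#' specific word). Word-type-conditional rates (e.g. predicting the noun
#' after a verb) restrict positions by the current and/or next token's type
#' tag.
#'
#' @param model A `cann_circuit` or `cann_fit`.
#' @param corpus Encoded `cann_corpus` (with `code`, and `type` when
#'   conditioning).
#' @param k Candidate-list size (default 5).
#' @param prev_type If given, keep only positions whose current token has
#'   this type tag (e.g. `"verb"`).
#' @param target_type If given, keep only positions whose next token has this
#'   type tag (e.g. `"noun"`).
#' @param target_role If given, keep only positions whose next token has this
#'   role label; `target_type = "noun", target_role = "O"` scores the
#'   prediction of a verb's object head noun.
#' @return Percentage of hits over eligible positions.
#' @export
correct_rate <- function(model, corpus, k = 5L, prev_type = NULL,
                         target_type = NULL, target_role = NULL) {
  circuit <- as_circuit(model)
  unk <- circuit$arch$n_input
  code_list <- sentence_list(corpus)
  type_list <- if (!is.null(prev_type) || !is.null(target_type)) {
    sentence_list(corpus, "type")
  }
  role_list <- if (!is.null(target_role)) sentence_list(corpus, "role")
  hits <- 0L; elig <- 0L
  for (s in seq_along(code_list)) {
    codes <- code_list[[s]]
    t_n <- length(codes) - 1L
    if (t_n < 1L) next
    out <- forward_sentence(circuit, codes)$output
    for (t in seq_len(t_n)) {
      if (codes[t + 1L] == unk) next
      if (!is.null(prev_type) && type_list[[s]][t] != prev_type) next
      if (!is.null(target_type) && type_list[[s]][t + 1L] != target_type) next
      if (!is.null(target_role) && role_list[[s]][t + 1L] != target_role) next
      elig <- elig + 1L
      if (codes[t + 1L] %in% topk_candidates(out[t, ], k)) hits <- hits + 1L
    }
  }
  if (!elig) {
    abort("No eligible prediction positions: every candidate position had an UNK target or failed the word-type condition.")
  }
  100 * hits / elig
}

#' Layer activity over a labelled evaluation corpus
#'
#' Feeds every labelled sentence through the model and collects the
#' per-word-position activity of one layer together with the token's role and
#' type labels -- the matrix the separability and PCA analyses operate on
#' (e.g. 1328 positions x 192 Purkinje cells at full scale).
#'
#' For a convergent bank, `"purkinje"` and `"output"` activities of the
#' requested `modules` (default: the ranked top five, if scores exist,
#' otherwise all) are concatenated column-wise.
#'
#' @param model A `cann_circuit`, `cann_fit`, `cann_bank` or
#'   `cann_convergent_fit`.
#' @param corpus Encoded, labelled `cann_corpus`.
#' @param layer `"input"` (one-hot), `"purkinje"` or `"output"`.
#' @param modules Module indices (bank models only).
#' @return An object of class `activity_matrix`: list with `values` (numeric
#'   matrix, one row per word position), `labels` (tibble: `sentence`,
#'   `position`, `token`, `role`, `type`, `code`) and `layer`.
#' @export
activity_matrix <- function(model, corpus,
                            layer = c("purkinje", "input", "output"),
                            modules = NULL) {
  layer <- match.arg(layer)
  labels <- tibble(sentence = corpus$sentence, position = corpus$position,
                   token = corpus$token, role = corpus$role,
                   type = corpus$type, code = corpus$code)
  code_list <- sentence_list(corpus)
  if (inherits(model, c("cann_bank", "cann_convergent_fit"))) {
    bank <- if (inherits(model, "cann_convergent_fit")) model$bank else model
    if (is.null(modules)) {
      modules <- if (!is.null(bank$module_scores)) {
        rank_and_select_modules(bank, min(5L, bank$n_modules))
      } else {
        seq_len(bank$n_modules)
      }
    }
    if (layer == "input") {
      values <- one_hot_matrix(unlist(code_list), bank$vocab$unk_index)
    } else {
      per_mod <- lapply(bank$modules[modules], function(m) {
        do.call(rbind, lapply(code_list, function(codes) {
          forward_sentence(m, codes)[[layer]]
        }))
      })
      values <- do.call(cbind, per_mod)
    }
  } else {
    circuit <- as_circuit(model)
    if (layer == "input") {
      values <- one_hot_matrix(unlist(code_list), circuit$arch$n_input)
    } else {
      values <- do.call(rbind, lapply(code_list, function(codes) {
        forward_sentence(circuit, codes)[[layer]]
      }))
    }
  }
  structure(list(values = values, labels = labels, layer = layer),
            class = "activity_matrix")
}

one_hot_matrix <- function(codes, n) {
  m <- matrix(0, length(codes), n)
  m[cbind(seq_along(codes), codes)] <- 1
  m
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> layer '%s': %d word positions x %d cells\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Principal-component projection of layer activity
#'
#' Centred PCA of an activity matrix, compressing the cell dimensions into the
#' few directions that maximally preserve the variance of the word-position
#' points (used for trajectory visualisation).
#'
#' @param matrix An `activity_matrix`.
#' @param n_components Number of components to project onto (2 or 3 for
#'   plots).
#' @return A list of class `cann_pca`: `coordinates` (tibble of `PC1..PCn`
#'   plus the position labels), `basis` (cells x n_components, unit columns),
#'   `rotation` (the complete orthonormal basis), `explained_variance`
#'   (fractions, non-increasing) and `center`.
#' @export
pca_project <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "activity_matrix"))
  n_components <- as.integer(n_components)
  if (nrow(matrix$values) <= n_components) {
    abort("Need more word positions than components.")
  }
  vars <- apply(matrix$values, 2, stats::var)
  if (all(vars < 1e-300)) abort("Activity matrix has zero variance.")
  pc <- stats::prcomp(matrix$values, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  structure(list(
    coordinates = dplyr::bind_cols(coords, matrix$labels),
    basis = pc$rotation[, seq_len(n_components), drop = FALSE],
    rotation = pc$rotation,
    explained_variance = ev,
    center = pc$center,
    layer = matrix$layer),
    class = "cann_pca")
}

# Rows usable for role contrasts: S/V/O-labelled positions only.
svo_rows <- function(am) {
  which(am$labels$role %in% c("S", "V", "O"))
}

#' Role separability by a repeated-split kernel SVM
#'
#' Quantifies how much subject/verb/object information a layer's activity
#' carries: for a contrast such as "S vs V/O", sentences are split 90/10, an
#' RBF-kernel support-vector machine is trained on the 90% and scored on the
#' held-out 10%, and the split is redrawn `n_repeats` times (default 256);
#' the report gives the mean held-out accuracy. Splits are drawn at the
#' sentence level so correlated positions from one sentence never straddle
#' the split. Only S/V/O-labelled positions enter the contrast; chance is 50%
#' for balanced classes. Splits leaving a training class empty (or an empty
#' test set) are redrawn and counted.
#'
#' @param matrix An `activity_matrix`.
#' @param contrast Character vector of target roles; each yields a
#'   one-vs-rest contrast among S/V/O rows (default all three).
#' @param n_repeats Number of random splits (default 256).
#' @param train_fraction Training fraction of sentences (default 0.9).
#' @param seed Integer seed for the split sequence.
#' @param cost,gamma RBF-SVM hyperparameters; `gamma = NULL` uses the
#'   variance-scaled default width `1 / (ncells * var(x))` (the scikit-learn
#'   `"scale"` heuristic), falling back to `1/ncells` for degenerate
#'   matrices.
#' @return A tibble of class `separation_report`: `layer`, `contrast`,
#'   `mean_accuracy` (%), `sd_accuracy`, `n_repeats`, `n_positions`,
#'   `n_redraws`, `seed`.
#' @export
svm_separation <- function(matrix, contrast = c("S", "V", "O"),
                           n_repeats = 256L, train_fraction = 0.9,
                           seed = 1L, cost = 1, gamma = NULL) {
  stopifnot(inherits(matrix, "activity_matrix"))
  rows <- svo_rows(matrix)
  if (!length(rows)) abort("No S/V/O-labelled positions in the matrix.")
  x <- matrix$values[rows, , drop = FALSE]
  roles <- matrix$labels$role[rows]
  sent <- matrix$labels$sentence[rows]
  sent_ids <- unique(sent)
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(x))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  out <- lapply(contrast, function(ct) {
    if (!any(roles == ct) || all(roles == ct)) {
      abort(sprintf("Contrast '%s' needs both classes present.", ct))
    }
    y <- factor(ifelse(roles == ct, ct, "rest"), levels = c(ct, "rest"))
    accs <- numeric(n_repeats)
    redraws <- 0L
    with_seed(derive_seed(seed, match(ct, c("S", "V", "O"), nomatch = 4L)), {
      for (r in seq_len(n_repeats)) {
        repeat {
          tr_sent <- sample(sent_ids, round(length(sent_ids) * train_fraction))
          tr <- sent %in% tr_sent
          if (length(unique(y[tr])) == 2L && any(!tr)) break
          redraws <- redraws + 1L
          if (redraws > 100L * n_repeats) {
            abort("Could not draw a split with both classes present.")
          }
        }
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = cost, gamma = gamma, scale = FALSE)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        accs[r] <- mean(pred == y[!tr])
      }
    })
    tibble(layer = matrix$layer, contrast = ct,
           mean_accuracy = 100 * mean(accs),
           sd_accuracy = 100 * stats::sd(accs),
           n_repeats = as.integer(n_repeats),
           n_positions = length(rows),
           n_redraws = redraws,
           seed = as.integer(seed))
  })
  structure(dplyr::bind_rows(out),
            class = c("separation_report", class(tibble())))
}

#' Linear separating direction for a role contrast
#'
#' Fits a linear maximum-margin classifier to a one-vs-rest role contrast and
#' returns the unit normal of its separating hyperplane -- the axis in cell
#' space "best suited for the separation", used as a plotting dimension. The
#' sign convention puts the contrast's target class on the positive side.
#'
#' @param matrix An `activity_matrix`.
#' @param contrast Target role (`"S"`, `"V"` or `"O"`).
#' @param cost SVM cost parameter.
#' @return Unit-norm numeric vector of length `ncells`.
#' @export
linear_separating_direction <- function(matrix, contrast, cost = 1) {
  stopifnot(inherits(matrix, "activity_matrix"))
  rows <- svo_rows(matrix)
  x <- matrix$values[rows, , drop = FALSE]
  roles <- matrix$labels$role[rows]
  if (!any(roles == contrast) || all(roles == contrast)) {
    abort(sprintf("Contrast '%s' needs both classes present.", contrast))
  }
  y <- factor(ifelse(roles == contrast, contrast, "rest"),
              levels = c(contrast, "rest"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  w <- w / sqrt(sum(w^2))
  if (mean(x[y == contrast, , drop = FALSE] %*% w) <
      mean(x[y != contrast, , drop = FALSE] %*% w)) {
    w <- -w
  }
  w
}

#' Similarity of a separating direction to PCA dimensions
#'
#' The squared dot product between a unit separating direction and each unit
#' PCA basis vector. Squaring makes the entries sum to 1 over a complete
#' orthonormal basis, so each entry is the fraction of the direction carried
#' by that principal component.
#'
#' @param direction Unit vector in cell space.
#' @param pca_basis Matrix whose columns are orthonormal basis vectors (e.g.
#'   the `rotation` of [pca_project()]), or a `cann_pca` object.
#' @return A tibble with `dimension` and `similarity` columns.
#' @export
similarity_index <- function(direction, pca_basis) {
  if (inherits(pca_basis, "cann_pca")) pca_basis <- pca_basis$rotation
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6) {
    abort("`direction` must have unit norm.")
  }
  norms <- sqrt(colSums(pca_basis^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("`pca_basis` columns must have unit norm.")
  }
  tibble(dimension = seq_len(ncol(pca_basis)),
         similarity = drop(crossprod(pca_basis, direction))^2)
}

#' Synaptic weight distribution of the input-Purkinje connection
#'
#' Summarises the weights of the parallel-fibre analogue (input cell to
#' Purkinje cell synapses): histogram, positive/negative fractions, the
#' fraction of near-zero "silent" synapses (`|w| < tau`), and a half-normal
#' scale fitted to the positive part (the physiological parallel-fibre weight
#' distribution is approximately half-normal with a peak of silent synapses).
#' For the excitatory/inhibitory-split variant, statistics are reported per
#' sub-population.
#'
#' @param circuit A `cann_circuit` or `cann_fit`.
#' @param tau Silent-synapse threshold; default 2% of the pooled weight
#'   standard deviation.
#' @param bins Number of histogram bins.
#' @return A list of class `weight_stats`: `summary` (tibble, one row per
#'   sub-population) and `histogram` (tibble: `population`, `mid`, `count`).
#' @export
weight_distribution_stats <- function(circuit, tau = NULL, bins = 60L) {
  circuit <- as_circuit(circuit)
  pops <- if (circuit$variant == "ei-split-input") {
    list(excitatory = as.numeric(circuit$W_exc),
         inhibitory = as.numeric(circuit$W_inh))
  } else {
    list(all = as.numeric(circuit$W_ff))
  }
  tau <- tau %||% (0.02 * stats::sd(unlist(pops)))
  summarise_pop <- function(w) {
    pos <- w[w > 0]
    tibble(n = length(w),
           frac_positive = mean(w > 0),
           frac_negative = mean(w < 0),
           frac_silent = mean(abs(w) < tau),
           sd = stats::sd(w),
           half_normal_sigma = if (length(pos)) sqrt(mean(pos^2)) else NA_real_)
  }
  summary <- dplyr::bind_rows(lapply(pops, summarise_pop), .id = "population")
  breaks <- seq(min(unlist(pops)), max(unlist(pops)), length.out = bins + 1L)
  histogram <- dplyr::bind_rows(lapply(pops, function(w) {
    h <- graphics::hist(w, breaks = breaks, plot = FALSE)
    tibble(mid = h$mids, count = h$counts)
  }), .id = "population")
  structure(list(summary = summary, histogram = histogram, tau = tau),
            class = "weight_stats")
}

#' @export
print.weight_stats <- function(x, ...) {
  cat(sprintf("<weight_stats> silent-synapse threshold tau = %.4g\n", x$tau))
  print(x$summary)
  invisible(x)
}
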