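#' Softmax prediction distribution
#'
#' Converts output-cell activities into next-word probabilities,
#' `P_i = exp(O_i) / sum(exp(O_i))`, using the shift-invariant numerically
#' stable form.
#'
#' @param output Numeric vector of output-cell activities.
#' @return A probability vector of the same length (sums to 1).
#' @export
softmax <- function(output) {
  if (any(!is.finite(output))) abort("`output` must be finite.")
  z <- exp(output - max(output))
  z / sum(z)
}

#' Climbing-fiber prediction error
#'
#' The cross-entropy between the one-hot correct-answer signal and the
#' softmax prediction reduces to the negative log probability assigned to the
#' actual next word: `E = -log(P_j)`. It is zero exactly when the circuit
#' predicts the next word with certainty, and increases as `P_j` shrinks.
#' Probabilities at 0 are clipped to `floor` (with a warning) so the error
#' stays finite.
#'
#' @param target Index `j` of the actual next word, or a one-hot vector.
#' @param p Prediction distribution from [softmax()].
#' @param floor Clipping floor for `P_j` (default `1e-12`).
#' @return Scalar prediction error, `>= 0`.
#' @export
prediction_error <- function(target, p, floor = 1e-12) {
  j <- if (length(target) > 1L) which(target == 1) else as.integer(target)
  if (length(j) != 1L || is.na(j) || j < 1L || j > length(p)) {
    abort("`target` must identify exactly one output cell.")
  }
  pj <- p[j]
  if (pj <= 0) {
    warn(sprintf("P_j = %g clipped to floor %g.", pj, floor))
    pj <- floor
  }
  -log(pj)
}

#' Training configuration
#'
#' @param learning_rate Step size for the gradient-descending synaptic
#'   update `W <- W - learning_rate * dE/dW` (gradients are averaged per
#'   prediction position within a batch).
#' @param epochs Number of laps over the training sentences (default 8, the
#'   point at which prediction performance plateaus).
#' @param batch_size Sentences per update (default 32).
#' @param seed Seed controlling shuffling (and any optimizer randomness).
#' @param optimizer `"plain-sgd"` (default; faithful to the plain
#'   gradient-descent rule and bitwise reproducible) or `"adaptive"` (Adam,
#'   for speed on large corpora).
#' @param bptt Credit assignment through time: `"full-within-sentence"`
#'   backpropagates through the recurrent pathway across the (at most 16)
#'   words of the sentence; `"one-step"` treats the incoming recurrent
#'   activity at each word as a constant.
#' @param evals_per_epoch Validation evaluations per lap (default 1).
#' @param top_k Candidate-list size for the validation correct rate.
#' @param max_batches Optional cap on the total number of update steps (used
#'   to inspect very early learning); `NULL` for no cap.
#' @param audit_signs If `TRUE`, verify the variant's sign constraints after
#'   every synaptic update and abort on any violation.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, epochs = 8L, batch_size = 32L,
                         seed = 1L,
                         optimizer = c("plain-sgd", "adaptive"),
                         bptt = c("full-within-sentence", "one-step"),
                         evals_per_epoch = 1L, top_k = 5L,
                         max_batches = NULL, audit_signs = FALSE) {
  check_scalar_number(learning_rate, "learning_rate", 0)
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  check_scalar_number(epochs, "epochs", 0)
  check_scalar_number(batch_size, "batch_size", 1)
  structure(list(learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 optimizer = match.arg(optimizer),
                 bptt = match.arg(bptt),
                 evals_per_epoch = as.integer(evals_per_epoch),
                 top_k = as.integer(top_k),
                 max_batches = max_batches,
                 audit_signs = isTRUE(audit_signs)),
            class = "train_config")
}

#' Gradients of the sentence prediction error
#'
#' Computes `dE/dW` and `dE/db` of the summed per-word prediction error with
#' respect to every trainable connection (input-to-Purkinje, recurrent-input
#' to Purkinje, Purkinje-to-output, their biases, and the relay connections in
#' the `"rec-compress"` variant). With `bptt = "full-within-sentence"` the
#' chain rule passes through the recurrent pathway across the whole sentence;
#' fixed identity relays never receive a gradient.
#'
#' @param circuit A `cann_circuit`.
#' @param codes Integer code vector of one sentence (length >= 2, so at least
#'   one prediction target exists).
#' @param bptt `"full-within-sentence"` or `"one-step"`.
#' @return A list with `grads` (named list of matrices/vectors matching the
#'   circuit's trainable fields), scalar `loss` (summed over positions) and
#'   `n_positions`.
#' @export
compute_gradients <- function(circuit, codes,
                              bptt = c("full-within-sentence", "one-step")) {
  bptt <- match.arg(bptt)
  if (is.data.frame(codes)) codes <- codes$code
  codes <- as.integer(codes)
  t_n <- length(codes) - 1L            # prediction positions
  if (t_n < 1L) abort("Sentence must have at least 2 words to form a target.")
  arch <- circuit$arch
  al_p <- circuit$alpha$purkinje
  al_r <- circuit$alpha$relay
  compress <- circuit$variant == "rec-compress"

  # ---- forward pass with cached pre-activations -------------------------
  A <- matrix(0, arch$n_purkinje, t_n)      # Purkinje pre-activation
  P <- matrix(0, arch$n_purkinje, t_n)
  Pr <- matrix(0, arch$n_output, t_n)       # softmax probabilities
  Xprev <- matrix(0, arch$n_rec_in, t_n)    # recurrent input at each word
  if (compress) {
    Cpre <- matrix(0, arch$n_rec_out, t_n)
    R1 <- matrix(0, arch$n_rec_out, t_n)
    Dpre <- matrix(0, arch$n_rec_in, t_n)
  }
  x_rec <- numeric(arch$n_rec_in)           # reset state
  loss <- 0
  for (t in seq_len(t_n)) {
    Xprev[, t] <- x_rec
    a <- ff_column(circuit, codes[t]) + drop(circuit$W_rec %*% x_rec) +
      circuit$b_p
    p <- leaky_relu(a, al_p)
    o <- leaky_relu(drop(circuit$W_out %*% p) + circuit$b_out,
                    circuit$alpha$output)
    pr <- softmax(o)
    A[, t] <- a; P[, t] <- p; Pr[, t] <- pr
    loss <- loss - log(max(pr[codes[t + 1L]], 1e-300))
    if (t < t_n) {
      if (compress) {
        cpre <- drop(circuit$W_c %*% p); r1 <- leaky_relu(cpre, al_r)
        dpre <- drop(circuit$W_d %*% r1); x_rec <- leaky_relu(dpre, al_r)
        Cpre[, t] <- cpre; R1[, t] <- r1; Dpre[, t] <- dpre
      } else {
        x_rec <- leaky_relu(leaky_relu(p, al_r), al_r)
      }
    }
  }

  # ---- backward pass ----------------------------------------------------
  Da <- matrix(0, arch$n_purkinje, t_n)     # dE/d(Purkinje pre-activation)
  Do <- Pr
  for (t in seq_len(t_n)) {
    j <- codes[t + 1L]
    Do[j, t] <- Do[j, t] - 1                # softmax + cross-entropy
  }
  gW_c <- if (compress) matrix(0, arch$n_rec_out, arch$n_purkinje)
  gW_d <- if (compress) matrix(0, arch$n_rec_in, arch$n_rec_out)
  for (t in rev(seq_len(t_n))) {
    d_p <- drop(crossprod(circuit$W_out, Do[, t]))
    if (bptt == "full-within-sentence" && t < t_n) {
      d_xrec <- drop(crossprod(circuit$W_rec, Da[, t + 1L]))
      if (compress) {
        d_dpre <- d_xrec * leaky_relu_grad(Dpre[, t], al_r)
        gW_d <- gW_d + tcrossprod(d_dpre, R1[, t])
        d_r1 <- drop(crossprod(circuit$W_d, d_dpre))
        d_cpre <- d_r1 * leaky_relu_grad(Cpre[, t], al_r)
        gW_c <- gW_c + tcrossprod(d_cpre, P[, t])
        d_p <- d_p + drop(crossprod(circuit$W_c, d_cpre))
      } else {
        # two identity relay hops, leaky slope applied at each
        s <- leaky_relu_grad(P[, t], al_r)^2
        d_p <- d_p + d_xrec * s
      }
    }
    Da[, t] <- d_p * leaky_relu_grad(A[, t], al_p)
  }

  gW_ff <- matrix(0, arch$n_purkinje, arch$n_input)
  for (t in seq_len(t_n)) {
    gW_ff[, codes[t]] <- gW_ff[, codes[t]] + Da[, t]
  }
  grads <- list(
    W_rec = tcrossprod(Da, Xprev),
    b_p = rowSums(Da),
    W_out = tcrossprod(Do, P),
    b_out = rowSums(Do))
  if (circuit$variant == "ei-split-input") {
    grads$W_exc <- gW_ff
    grads$W_inh <- gW_ff
  } else {
    grads$W_ff <- gW_ff
  }
  if (compress) {
    grads$W_c <- gW_c
    grads$W_d <- gW_d
  }
  list(grads = grads[trainable_fields(circuit)], loss = loss,
       n_positions = t_n)
}

#' Apply a gradient-descending synaptic update
#'
#' Performs `W <- W - epsilon * dE/dW` on every trainable connection, then
#' projects sign-constrained connections back onto their cone (clipping at
#' zero), so constraints hold after every update.
#'
#' @param circuit A `cann_circuit`.
#' @param grads Named gradient list from [compute_gradients()].
#' @param epsilon Learning rate (>= 0).
#' @return The updated circuit.
#' @export
apply_update <- function(circuit, grads, epsilon) {
  check_scalar_number(epsilon, "epsilon", 0)
  for (nm in names(grads)) {
    circuit[[nm]] <- circuit[[nm]] - epsilon * grads[[nm]]
  }
  enforce_signs(circuit)
}

# Sum two gradient lists elementwise.
add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (nm in names(g2)) g1[[nm]] <- g1[[nm]] + g2[[nm]]
  g1
}

scale_grads <- function(g, s) lapply(g, function(m) m * s)

# Validation metrics: mean per-position cross entropy (all targets, including
# UNK) and top-k correct rate (UNK targets excluded, as in evaluation).
evaluate_circuit <- function(circuit, code_list, unk_index, k = 5L) {
  ce_sum <- 0; ce_n <- 0L; hits <- 0L; elig <- 0L
  for (codes in code_list) {
    t_n <- length(codes) - 1L
    if (t_n < 1L) next
    out <- forward_sentence(circuit, codes)$output
    for (t in seq_len(t_n)) {
      pr <- softmax(out[t, ])
      j <- codes[t + 1L]
      ce_sum <- ce_sum - log(max(pr[j], 1e-300))
      ce_n <- ce_n + 1L
      if (j != unk_index) {
        elig <- elig + 1L
        top <- topk_candidates(out[t, ], k)
        if (j %in% top) hits <- hits + 1L
      }
    }
  }
  list(cross_entropy = if (ce_n) ce_sum / ce_n else NA_real_,
       top_k_rate = if (elig) 100 * hits / elig else NA_real_)
}

#' Train a circuit on next-word prediction
#'
#' Runs `epochs` laps over the (seeded-shuffled) training sentences. Each
#' batch accumulates the gradients of the prediction error over its
#' sentences, averages per prediction position, and applies the
#' gradient-descending synaptic update; sign constraints are re-imposed after
#' every step. Validation cross entropy and top-k correct rate are logged at
#' seeded intervals, starting with the untrained circuit.
#'
#' @param circuit A `cann_circuit` whose input width matches the vocabulary.
#' @param split A `corpus_split` of encoded sentences.
#' @param config A [train_config()].
#' @param vocab The `cann_vocabulary` (used to exclude UNK targets from the
#'   validation correct rate).
#' @return An object of class `cann_fit` with elements `circuit` (trained),
#'   `log` (tibble: `epoch`, `fraction_of_lap`, `val_cross_entropy`,
#'   `val_top5_rate`, `seed`), `config` and `vocab`.
#' @export
train_cann <- function(circuit, split, config = train_config(), vocab) {
  stopifnot(inherits(circuit, "cann_circuit"),
            inherits(split, "corpus_split"),
            inherits(config, "train_config"))
  unk <- if (!missing(vocab)) vocab$unk_index else circuit$arch$n_input
  train_codes <- sentence_list(split$train)
  val_codes <- sentence_list(split$validation)
  train_codes <- train_codes[lengths(train_codes) >= 2L]
  n_train <- length(train_codes)
  if (!n_train) abort("No trainable sentences (all shorter than 2 words).")

  log_rows <- list()
  log_point <- function(epoch, frac) {
    ev <- evaluate_circuit(circuit, val_codes, unk, config$top_k)
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      epoch = epoch, fraction_of_lap = frac,
      val_cross_entropy = ev$cross_entropy,
      val_top5_rate = ev$top_k_rate, seed = config$seed)
  }
  log_point(0L, 0)

  adam <- NULL
  if (config$optimizer == "adaptive") {
    adam <- list(m = list(), v = list(), t = 0L,
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  }
  n_batches_done <- 0L
  stop_early <- FALSE
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      if (stop_early) break
      ord <- sample.int(n_train)
      starts <- seq(1L, n_train, by = config$batch_size)
      eval_after <- unique(pmax(1L, round(
        seq_len(config$evals_per_epoch) / config$evals_per_epoch *
          length(starts))))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_train)]
        acc <- NULL; n_pos <- 0L; batch_loss <- 0
        for (si in idx) {
          g <- tryCatch(
            compute_gradients(circuit, train_codes[[si]], bptt = config$bptt),
            error = function(e) {
              if (grepl("finite", conditionMessage(e))) {
                abort(sprintf(
                  "Training diverged (non-finite activity) at epoch %d, batch %d.",
                  epoch, bi))
              }
              stop(e)
            })
          acc <- add_grads(acc, g$grads)
          n_pos <- n_pos + g$n_positions
          batch_loss <- batch_loss + g$loss
        }
        if (!is.finite(batch_loss)) {
          abort(sprintf("Training diverged (non-finite loss) at epoch %d, batch %d.",
                        epoch, bi))
        }
        acc <- scale_grads(acc, 1 / n_pos)
        if (config$optimizer == "adaptive") {
          adam$t <- adam$t + 1L
          for (nm in names(acc)) {
            g1 <- acc[[nm]]
            adam$m[[nm]] <- if (is.null(adam$m[[nm]])) (1 - adam$beta1) * g1 else
              adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * g1
            adam$v[[nm]] <- if (is.null(adam$v[[nm]])) (1 - adam$beta2) * g1^2 else
              adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * g1^2
            mhat <- adam$m[[nm]] / (1 - adam$beta1^adam$t)
            vhat <- adam$v[[nm]] / (1 - adam$beta2^adam$t)
            acc[[nm]] <- mhat / (sqrt(vhat) + adam$eps)
          }
        }
        circuit <- apply_update(circuit, acc, config$learning_rate)
        if (config$audit_signs && !signs_ok(circuit)) {
          abort(sprintf("Sign-constraint violation after update at epoch %d, batch %d.",
                        epoch, bi))
        }
        n_batches_done <- n_batches_done + 1L
        if (bi %in% eval_after) {
          log_point(epoch, bi / length(starts))
        }
        if (!is.null(config$max_batches) &&
            n_batches_done >= config$max_batches) {
          if (!(bi %in% eval_after)) log_point(epoch, bi / length(starts))
          stop_early <- TRUE
          break
        }
      }
    }
  })
  structure(list(circuit = circuit,
                 log = dplyr::bind_rows(log_rows),
                 config = config,
                 vocab = if (!missing(vocab)) vocab else NULL),
            class = "cann_fit")
}

#' @export
print.cann_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  cat(sprintf("<cann_fit> %s circuit, %d epochs; final validation: cross entropy %.3f, top-%d rate %.1f%%\n",
              x$circuit$variant, max(x$log$epoch), last$val_cross_entropy,
              x$config$top_k, last$val_top5_rate))
  invisible(x)
}
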