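#' Leaky rectified linear activation
#'
#' The input/output function of every cell in the circuit:
#' `y = x` for `x >= 0` and `y = alpha * x` for `x < 0`. With `alpha = 1` the
#' map is exactly the identity (linear transmission, as assumed for the
#' Purkinje-to-output connection); with `alpha = 0` it is the fully rectifying
#' ReLU.
#'
#' @param x Numeric vector or matrix.
#' @param alpha Leak slope in `[0, 1]`.
#' @return `x` transformed elementwise.
#' @export
leaky_relu <- function(x, alpha) {
  check_scalar_number(alpha, "alpha", 0, 1)
  if (alpha == 1) return(x)
  neg <- x < 0
  x[neg] <- alpha * x[neg]
  x
}

# Derivative of leaky_relu with respect to its input (subgradient 1 at 0).
leaky_relu_grad <- function(x, alpha) {
  g <- rep.int(1, length(x))
  g[x < 0] <- alpha
  g
}

glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Construct a cerebellar prediction circuit
#'
#' Builds the three-layer circuit: a one-hot input layer (granule cells, one
#' cell per vocabulary word plus the UNK cell), a Purkinje middle layer, an
#' output layer (nucleus neurons), and a recurrent pathway that relays
#' Purkinje activity back to a distinct population of recurrent input cells.
#' All connections implement `F(W x + b)` with leaky-ReLU `F`; the slope is
#' 0.14 into the Purkinje cells and along the recurrent relays, and 1.0
#' (linear) from Purkinje cells to the output cells. In the `"original"`
#' variant the two recurrent relay connections are fixed identity maps with
#' zero bias.
#'
#' Variants add further biological constraints:
#' \describe{
#'   \item{`"original"`}{identity relays, unconstrained signs.}
#'   \item{`"rec-compress"`}{the relay is replaced by trainable
#'     compression/decompression connections (Purkinje -> `n_rec_out` cells ->
#'     `n_rec_in` cells; defaults `n_purkinje/4` and `n_purkinje`, i.e. 48 and
#'     192 at full scale), modelling convergent Purkinje-output and divergent
#'     output-input anatomy.}
#'   \item{`"inhib-purkinje-output"`}{Purkinje-to-output weights restricted to
#'     be nonpositive (GABAergic Purkinje output).}
#'   \item{`"ei-split-input"`}{the input-to-Purkinje projection is split into a
#'     nonnegative block (direct parallel-fibre excitation) and a nonpositive
#'     block (inhibition via molecular-layer interneurons).}
#' }
#'
#' @param n_input Number of input cells, `V + 1` (vocabulary plus UNK).
#' @param n_purkinje Number of Purkinje cells (192 at full scale).
#' @param n_output Number of output cells; defaults to `n_input` (one cell per
#'   word) as in the non-convergent circuit.
#' @param variant One of `"original"`, `"rec-compress"`,
#'   `"inhib-purkinje-output"`, `"ei-split-input"`.
#' @param seed Integer seed for the (Glorot-style symmetric uniform) weight
#'   initialization; sign-constrained blocks are initialized inside their cone.
#' @param n_rec_out,n_rec_in Recurrent-pathway population sizes; only used by
#'   `"rec-compress"` (other variants relay identically, so both equal
#'   `n_purkinje`).
#' @param alpha_purkinje,alpha_output,alpha_relay Leak slopes per connection.
#'
#' @return An object of class `cann_circuit`.
#' @export
build_circuit <- function(n_input, n_purkinje = 192L, n_output = n_input,
                          variant = c("original", "rec-compress",
                                      "inhib-purkinje-output",
                                      "ei-split-input"),
                          seed = 1L, n_rec_out = NULL, n_rec_in = NULL,
                          alpha_purkinje = 0.14, alpha_output = 1.0,
                          alpha_relay = 0.14) {
  variant <- match.arg(variant)
  check_scalar_number(n_input, "n_input", 1)
  check_scalar_number(n_purkinje, "n_purkinje", 1)
  check_scalar_number(n_output, "n_output", 1)
  n_input <- as.integer(n_input); n_purkinje <- as.integer(n_purkinje)
  n_output <- as.integer(n_output)
  if (variant == "rec-compress") {
    n_rec_out <- as.integer(n_rec_out %||% max(1L, n_purkinje %/% 4L))
    n_rec_in <- as.integer(n_rec_in %||% n_purkinje)
  } else {
    n_rec_out <- n_purkinje
    n_rec_in <- n_purkinje
  }
  circuit <- with_seed(seed, {
    cc <- list(
      arch = list(n_input = n_input, n_purkinje = n_purkinje,
                  n_output = n_output, n_rec_out = n_rec_out,
                  n_rec_in = n_rec_in),
      variant = variant,
      alpha = list(purkinje = alpha_purkinje, output = alpha_output,
                   relay = alpha_relay),
      seed = seed,
      blocked = FALSE,
      W_rec_saved = NULL)
    if (variant == "ei-split-input") {
      # two full-width blocks, each scaled so their sum has Glorot variance
      cc$W_exc <- abs(glorot(n_purkinje, n_input)) / sqrt(2)
      cc$W_inh <- -abs(glorot(n_purkinje, n_input)) / sqrt(2)
    } else {
      cc$W_ff <- glorot(n_purkinje, n_input)
    }
    cc$W_rec <- glorot(n_purkinje, n_rec_in)
    cc$b_p <- numeric(n_purkinje)
    cc$W_out <- if (variant == "inhib-purkinje-output") {
      -abs(glorot(n_output, n_purkinje))
    } else {
      glorot(n_output, n_purkinje)
    }
    cc$b_out <- numeric(n_output)
    if (variant == "rec-compress") {
      cc$W_c <- glorot(n_rec_out, n_purkinje)   # Purkinje -> recurrent output
      cc$W_d <- glorot(n_rec_in, n_rec_out)     # recurrent output -> input
    }
    cc
  })
  circuit$recurrent_activity <- numeric(n_rec_in)
  structure(circuit, class = "cann_circuit")
}

#' @export
print.cann_circuit <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<cann_circuit> variant=%s  %d -> %d -> %d (recurrent %d -> %d)%s\n",
              x$variant, a$n_input, a$n_purkinje, a$n_output,
              a$n_rec_out, a$n_rec_in,
              if (x$blocked) "  [recurrent pathway blocked]" else ""))
  invisible(x)
}

# Names of trainable weight/bias fields for a circuit. Relay connections are
# plastic only in the rec-compress variant.
trainable_fields <- function(circuit) {
  ff <- if (circuit$variant == "ei-split-input") c("W_exc", "W_inh") else "W_ff"
  c(ff, "W_rec", "b_p", "W_out", "b_out",
    if (circuit$variant == "rec-compress") c("W_c", "W_d"))
}

# Feedforward input->Purkinje drive for one one-hot coded word.
ff_column <- function(circuit, code) {
  if (circuit$variant == "ei-split-input") {
    circuit$W_exc[, code] + circuit$W_inh[, code]
  } else {
    circuit$W_ff[, code]
  }
}

# Relay map: Purkinje activity -> recurrent-input cell activity. Both relay
# hops apply the leaky-ReLU at the postsynaptic cell; biases on the relays are
# fixed at zero.
relay_forward <- function(circuit, p) {
  al <- circuit$alpha$relay
  if (circuit$variant == "rec-compress") {
    r1 <- leaky_relu(drop(circuit$W_c %*% p), al)
    leaky_relu(drop(circuit$W_d %*% r1), al)
  } else {
    leaky_relu(leaky_relu(p, al), al)
  }
}

#' Reset a circuit to its spontaneous (sentence-start) state
#'
#' Sets the persistent recurrent-input activity to the zero-input propagated
#' value (the zero vector, since relay biases are zero). The Purkinje activity
#' evaluated at this state with no word input, `F(b_p)`, is the spontaneous
#' activity used as the origin of trajectory plots.
#'
#' @param circuit A `cann_circuit`.
#' @return The circuit with reset recurrent state.
#' @export
reset_state <- function(circuit) {
  stopifnot(inherits(circuit, "cann_circuit"))
  circuit$recurrent_activity <- numeric(circuit$arch$n_rec_in)
  circuit
}

#' Spontaneous Purkinje activity
#'
#' Purkinje-layer activity under zero word input and reset recurrent state.
#'
#' @param circuit A `cann_circuit`.
#' @return Numeric vector of length `n_purkinje`.
#' @export
spontaneous_activity <- function(circuit) {
  leaky_relu(circuit$b_p, circuit$alpha$purkinje)
}

#' Present one word to the circuit
#'
#' Integrates the current word's feedforward drive with the persistent
#' recurrent signal carrying previous-word information:
#' `purkinje = F(W_ff one_hot(word) + W_rec recurrent_activity + b_p)` with
#' slope 0.14, then `output = F(W_out purkinje + b_out)` with slope 1.0
#' (linear). The Purkinje signal is relayed through the recurrent pathway and
#' persists as the recurrent-input activity until the next word. If the
#' recurrent pathway is blocked the Purkinje activity depends only on the
#' current word.
#'
#' @param circuit A `cann_circuit`.
#' @param code Input-cell index of the word (`1..V+1`).
#' @return A list with `circuit` (updated state), `purkinje` and `output`
#'   activity vectors.
#' @export
forward_step <- function(circuit, code) {
  stopifnot(inherits(circuit, "cann_circuit"))
  n_in <- circuit$arch$n_input
  if (!is.numeric(code) || length(code) != 1L || is.na(code) ||
      code < 1 || code > n_in) {
    abort(sprintf("`code` must be an input-cell index in 1..%d.", n_in))
  }
  if (is.null(circuit$recurrent_activity)) {
    abort("Circuit state is uninitialized; call reset_state() first.")
  }
  code <- as.integer(code)
  a <- ff_column(circuit, code) +
    drop(circuit$W_rec %*% circuit$recurrent_activity) + circuit$b_p
  p <- leaky_relu(a, circuit$alpha$purkinje)
  o <- leaky_relu(drop(circuit$W_out %*% p) + circuit$b_out,
                  circuit$alpha$output)
  circuit$recurrent_activity <- relay_forward(circuit, p)
  list(circuit = circuit, purkinje = p, output = o)
}

#' Run a full sentence through the circuit
#'
#' Resets the state, then presents the words sequentially and records the
#' activity of every layer after each word.
#'
#' @param circuit A `cann_circuit`.
#' @param codes Integer vector of input-cell indices (one sentence), or an
#'   encoded single-sentence `cann_corpus`.
#' @return A list with matrices `purkinje` (T x n_purkinje) and `output`
#'   (T x n_output), the input `codes`, and the final `circuit` state.
#' @export
forward_sentence <- function(circuit, codes) {
  if (is.data.frame(codes)) codes <- codes$code
  if (!length(codes)) abort("`codes` must contain at least one word.")
  circuit <- reset_state(circuit)
  t_len <- length(codes)
  P <- matrix(0, t_len, circuit$arch$n_purkinje)
  O <- matrix(0, t_len, circuit$arch$n_output)
  for (t in seq_len(t_len)) {
    step <- forward_step(circuit, codes[t])
    circuit <- step$circuit
    P[t, ] <- step$purkinje
    O[t, ] <- step$output
  }
  list(purkinje = P, output = O, codes = as.integer(codes), circuit = circuit)
}

#' Block or restore the recurrent pathway
#'
#' `block_recurrent()` zeroes the synaptic weights from the recurrent-input
#' cells to the Purkinje cells, ablating all context information so the
#' circuit encodes only the immediately preceding word. The original weights
#' are saved and `unblock_recurrent()` restores them bitwise. Both operations
#' are idempotent.
#'
#' @param circuit A `cann_circuit`.
#' @return The modified circuit.
#' @export
block_recurrent <- function(circuit) {
  stopifnot(inherits(circuit, "cann_circuit"))
  if (circuit$blocked) return(circuit)
  circuit$W_rec_saved <- circuit$W_rec
  circuit$W_rec <- matrix(0, nrow(circuit$W_rec), ncol(circuit$W_rec))
  circuit$blocked <- TRUE
  circuit
}

#' @rdname block_recurrent
#' @export
unblock_recurrent <- function(circuit) {
  stopifnot(inherits(circuit, "cann_circuit"))
  if (!circuit$blocked) return(circuit)
  circuit$W_rec <- circuit$W_rec_saved
  circuit$W_rec_saved <- NULL
  circuit$blocked <- FALSE
  circuit
}

# Project sign-constrained connections back onto their cone.
enforce_signs <- function(circuit) {
  if (circuit$variant == "inhib-purkinje-output") {
    circuit$W_out <- pmin(circuit$W_out, 0)
  }
  if (circuit$variant == "ei-split-input") {
    circuit$W_exc <- pmax(circuit$W_exc, 0)
    circuit$W_inh <- pmin(circuit$W_inh, 0)
  }
  circuit
}

# TRUE when all sign constraints hold (used by tests and training audits).
signs_ok <- function(circuit) {
  switch(circuit$variant,
         "inhib-purkinje-output" = max(circuit$W_out) <= 0,
         "ei-split-input" = min(circuit$W_exc) >= 0 && max(circuit$W_inh) <= 0,
         TRUE)
}
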