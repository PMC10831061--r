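#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted circuit
#'
#' @param x A `cann_fit`.
#' @param ... Unused.
#' @return The validation log as a tibble (`epoch`, `fraction_of_lap`,
#'   `val_cross_entropy`, `val_top5_rate`, `seed`).
#' @export
tidy.cann_fit <- function(x, ...) {
  x$log
}

#' One-row summary of a fitted circuit
#'
#' @param x A `cann_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the architecture, variant, epochs trained
#'   and final validation metrics.
#' @export
glance.cann_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  tibble(variant = x$circuit$variant,
         n_input = x$circuit$arch$n_input,
         n_purkinje = x$circuit$arch$n_purkinje,
         n_output = x$circuit$arch$n_output,
         epochs = max(x$log$epoch),
         val_cross_entropy = last$val_cross_entropy,
         val_top5_rate = last$val_top5_rate,
         seed = x$config$seed)
}

#' Tidy per-module statistics of a convergent fit
#'
#' @param x A `cann_convergent_fit`.
#' @param ... Unused.
#' @return A tibble with one row per module: final-stretch decoding accuracy
#'   and winner-selection count.
#' @export
tidy.cann_convergent_fit <- function(x, ...) {
  x$bank$module_scores
}

#' One-row summary of a convergent fit
#'
#' @param x A `cann_convergent_fit`.
#' @param ... Unused.
#' @return A one-row tibble with module count, epochs and final validation
#'   top-k rate over all modules.
#' @export
glance.cann_convergent_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  tibble(n_modules = x$bank$n_modules,
         epochs = max(x$log$epoch),
         val_top5_rate_all = last$val_top5_rate_all,
         seed = x$config$seed)
}

#' Tidy weight-distribution statistics
#'
#' @param x A `weight_stats` object.
#' @param ... Unused.
#' @return The per-population summary tibble.
#' @export
tidy.weight_stats <- function(x, ...) {
  x$summary
}
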