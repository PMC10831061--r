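#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_path geom_hline facet_wrap labs theme_minimal position_dodge vars
#' @export
ggplot2::autoplot

#' Plot learning curves of a fitted circuit
#'
#' Validation cross entropy and top-k correct rate against training progress
#' (laps over the training sentences).
#'
#' @param object A `cann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cann_fit <- function(object, ...) {
  log <- object$log |>
    dplyr::mutate(lap = .data$epoch - 1 + .data$fraction_of_lap,
                  lap = pmax(.data$lap, 0)) |>
    tidyr::pivot_longer(c("val_cross_entropy", "val_top5_rate"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         val_cross_entropy = "cross entropy",
                                         val_top5_rate = "top-5 correct rate (%)"))
  ggplot(log, aes(x = .data$lap, y = .data$value)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(vars(.data$metric), scales = "free_y", ncol = 1) +
    labs(x = "training laps", y = NULL,
         title = "Validation performance during training") +
    theme_minimal()
}

#' Plot a role-separability report
#'
#' Mean held-out separation accuracy per layer and contrast, with the 50%
#' chance line.
#'
#' @param object A `separation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separation_report <- function(object, ...) {
  ggplot(object, aes(x = .data$contrast, y = .data$mean_accuracy,
                     fill = .data$layer)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_hline(yintercept = 50, linetype = "dashed", colour = "grey40") +
    labs(x = "role contrast (one vs rest)", y = "separation accuracy (%)",
         title = "Syntactic role separability by layer") +
    theme_minimal()
}

#' Plot layer-activity trajectories in PCA space
#'
#' Word-by-word activity transitions projected on the first two principal
#' components, one path per sentence, coloured by syntactic role.
#'
#' @param object A `cann_pca` (from [pca_project()] with
#'   `n_components >= 2`).
#' @param sentences Optional sentence ids to draw (default: first 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cann_pca <- function(object, sentences = NULL, ...) {
  coords <- object$coordinates
  ids <- sentences %||% utils::head(unique(coords$sentence), 8)
  coords <- dplyr::filter(coords, .data$sentence %in% ids)
  ggplot(coords, aes(x = .data$PC1, y = .data$PC2,
                     group = .data$sentence)) +
    geom_path(colour = "grey70") +
    geom_point(aes(colour = .data$role), size = 2) +
    labs(title = sprintf("%s-layer activity trajectories", object$layer),
         x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
}

#' Plot a synaptic weight distribution
#'
#' Histogram of input-to-Purkinje weights, one panel per sub-population.
#'
#' @param object A `weight_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_stats <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = diff(object$histogram$mid[1:2]) * 0.95) +
    facet_wrap(vars(.data$population), scales = "free_y") +
    labs(x = "synaptic weight", y = "synapse count",
         title = "Input-Purkinje synaptic weight distribution") +
    theme_minimal()
}
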