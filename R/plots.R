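#' Plot a kernel response matrix as a heatmap
#'
#' @param object A [kernel_response_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kernel_response_matrix <- function(object, ...) {
  d <- tidy.kernel_response_matrix(object)
  d$kernel <- factor(d$kernel, levels = rev(rownames(object)))
  d$stimulus <- factor(d$stimulus, levels = colnames(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$stimulus, .data$kernel,
                                  fill = .data$response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "stimulus", y = "kernel",
                  fill = "ideal\nresponse") +
    ggplot2::theme_minimal()
}

#' Plot a double-Gaussian direction fit
#'
#' Per-angle mean responses with the fitted tuning curve overlaid.
#'
#' @param object A [fit_double_gaussian()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dg_fit <- function(object, ...) {
  pts <- tibble::tibble(angle = object$angles, response = object$means)
  grid <- tibble::tibble(angle = seq(0, 360, by = 2))
  grid$response <- predict.dg_fit(object, grid$angle)
  ggplot2::ggplot(pts, ggplot2::aes(.data$angle, .data$response)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, by = 90)) +
    ggplot2::labs(x = "direction (deg)", y = "response (dF/F)",
                  title = sprintf("theta_pref = %.1f deg, DI = %.2f",
                                  object$coefficients[["theta_pref"]],
                                  object$di)) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap delta distribution
#'
#' Histogram of the resampled differences with the percentile interval and
#' zero marked.
#'
#' @param object A [bootstrap_delta()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  d <- tibble::tibble(delta = object$deltas)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "firebrick") +
    ggplot2::labs(x = "bootstrap delta", y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter plot of sequence irregularity metrics
#'
#' Best-aligned correlation with forward versus backward motion for a
#' table of scored sequences, optionally highlighting chosen family
#' members.
#'
#' @param metrics Output of [sequence_metrics()].
#' @param highlight Optional character vector of `sequence_str` values to
#'   mark.
#' @return A ggplot object.
#' @export
plot_sequence_metrics <- function(metrics, highlight = NULL) {
  p <- ggplot2::ggplot(metrics, ggplot2::aes(.data$corr_F, .data$corr_B)) +
    ggplot2::geom_point(shape = 4, alpha = 0.3, colour = "grey40") +
    ggplot2::labs(x = "correlation with forward motion",
                  y = "correlation with backward motion") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    sel <- metrics[metrics$sequence_str %in% highlight, ]
    p <- p + ggplot2::geom_point(data = sel, colour = "steelblue", size = 3,
                                 shape = 1, stroke = 1.2)
  }
  p
}

#' Plot a principal-plane projection
#'
#' Input vectors and kernel reference points from [pca_project()] in the
#' shared 2-D plane, kernels labelled.
#'
#' @param projection Output of [pca_project()].
#' @return A ggplot object.
#' @export
plot_pca_projection <- function(projection) {
  kern <- projection[projection$type == "kernel", ]
  inp <- projection[projection$type == "input", ]
  ggplot2::ggplot(inp, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = kern, colour = "firebrick", shape = 17) +
    ggplot2::geom_text(data = kern, ggplot2::aes(label = .data$id),
                       vjust = -0.8, size = 3, colour = "firebrick") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
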