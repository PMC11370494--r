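#' Plot replicate-mean metrics across a sweep
#'
#' Line plot of the replicate-mean of a scoring metric against the swept
#' condition, one line per approach and estimate type.
#'
#' @param object A `cr_sweep` from one of the `run_*` experiment drivers.
#' @param metric Metric column to plot. Default `"mse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cr_sweep <- function(object, metric = "mse", ...) {
  swept <- attr(object, "swept")
  xvar <- swept[1]
  summary <- summarise_sweep(object)
  mean_col <- paste0("mean_", metric)
  summary$label <- paste(summary$approach, summary$estimate_type)
  facet <- setdiff(swept, xvar)

  x_discrete <- !is.numeric(summary[[xvar]])
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(
      x = .data[[xvar]], y = .data[[mean_col]],
      colour = .data$label,
      group = .data$label
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = paste("replicate-mean", metric),
                  colour = "estimator") +
    ggplot2::theme_minimal()
  if (!x_discrete) p <- p + ggplot2::geom_line()
  if (length(facet) > 0) {
    p <- p + ggplot2::facet_wrap(facet, labeller = ggplot2::label_both)
  }
  p
}

#' Scatter estimated against true resilience
#'
#' One panel per estimate type, with the identity line: unbiased estimation
#' places points on the diagonal, shrinkage tilts them below it.
#'
#' @param estimates Numeric vector of estimates, or the tibble returned in a
#'   `cr_inverse_fit` (columns `raw_residual` and `corrected_cr`).
#' @param cr_true Numeric vector of true resilience for the same samples.
#' @return A ggplot object.
#' @export
plot_calibration <- function(estimates, cr_true) {
  if (is.data.frame(estimates)) {
    df <- tidyr::pivot_longer(
      tibble::tibble(cr_true = cr_true,
                     raw = estimates$raw_residual,
                     corrected = estimates$corrected_cr),
      cols = c("raw", "corrected"),
      names_to = "estimate_type", values_to = "estimate"
    )
  } else {
    df <- tibble::tibble(cr_true = cr_true, estimate = estimates,
                         estimate_type = "estimate")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cr_true, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~estimate_type) +
    ggplot2::labs(x = "true resilience", y = "estimated resilience") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
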