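# ggplot2 displays for the pipeline's result types.

#' MA plot of a two-color replicate, before and after normalization
#'
#' Scatter of the log ratio M against average intensity A with the
#' fitted dye-bias trend, and the normalized log ratio alongside. Dye
#' bias shows as curvature of the point cloud about M = 0 in the raw
#' panel and should be gone after loess.
#'
#' @param normalized output of [normalize_arrays()] (or of
#'   [loess_normalize()] for one replicate).
#' @param max_points probes subsampled for display (default 20000).
#' @return A ggplot object.
#' @export
plot_ma <- function(normalized, max_points = 20000) {
  normalized <- tibble::as_tibble(normalized)
  if (!"replicate" %in% names(normalized)) normalized$replicate <- "rep1"
  if (nrow(normalized) > max_points) {
    normalized <- dplyr::slice_sample(normalized, n = max_points)
  }
  long <- tidyr::pivot_longer(normalized, c("M", "M_norm"),
                              names_to = "stage", values_to = "m") |>
    dplyr::mutate(stage = factor(.data$stage, c("M", "M_norm"),
                                 c("raw", "loess-normalized")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$A, y = .data$m)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_line(
      data = dplyr::filter(long, .data$stage == "raw"),
      ggplot2::aes(y = .data$dye_fit), colour = "red", linewidth = 0.6
    ) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$replicate), ggplot2::vars(.data$stage)
    ) +
    ggplot2::labs(x = "A (average log2 intensity)", y = "M (log2 ratio)",
                  title = "Dye-bias normalization")
}

#' Percent-change bar chart of trial traits
#'
#' Displays [percent_change_table()] results: one bar per trait cell,
#' the OPT-vs-FFP percent change, faceted by variety when present.
#'
#' @param pct output of [percent_change_table()].
#' @return A ggplot object.
#' @export
plot_percent_change <- function(pct) {
  pct <- tibble::as_tibble(pct)
  x_col <- if ("internode" %in% names(pct)) "internode" else "trait"
  p <- ggplot2::ggplot(pct, ggplot2::aes(
    x = factor(.data[[x_col]]), y = .data$pct_change
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = x_col, y = "% change (OPT vs FFP)")
  facets <- intersect(c("variety", "trait"), names(pct))
  facets <- setdiff(facets, x_col)
  if (length(facets)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(!!sym(facets[1])))
  }
  p
}

#' @describeIn qpcr_concordance Scatter of qPCR vs array log2 fold
#'   changes with the OLS fit and identity line.
#' @param object a `qpcr_concordance` object.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.qpcr_concordance <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$array_log2fc, y = .data$qpcr_log2fc
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "microarray log2 ratio", y = "qPCR log2 ratio",
      title = sprintf("qPCR concordance: R² = %.2f, slope = %.2f",
                      object$r.squared, object$slope)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
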