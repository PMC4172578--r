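#' Manhattan plot of a genome scan
#'
#' @param scan A `scan_result`.
#' @param threshold Optional p-value threshold drawn as a horizontal line
#'   (e.g. a Bonferroni threshold from [adjust_pvalues()]).
#' @param highlight Optional marker ids to emphasise (e.g. true QTNs).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, threshold = NULL, highlight = NULL) {
  df <- tibble::as_tibble(scan) |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(
      chromosome = factor(.data$chromosome,
                          levels = unique(scan$chromosome)),
      neglog_p = -log10(.data$p_value)
    )
  # cumulative genome coordinate per chromosome
  offsets <- df |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(len = max(.data$position), .groups = "drop") |>
    dplyr::mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  df <- dplyr::left_join(df, offsets, by = "chromosome") |>
    dplyr::mutate(coord = .data$position + .data$offset)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$coord, .data$neglog_p,
                                        colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(
      x = "Genome position", y = expression(-log[10](p)),
      title = sprintf("%s scan", attr(scan, "provenance")$method)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$marker %in% highlight),
      colour = "black", shape = 1, size = 2
    )
  }
  p
}

#' Quantile-quantile plot of scan p-values
#'
#' Observed versus expected -log10 p under the uniform null, annotated
#' with the genomic-control inflation factor.
#'
#' @param scan A `scan_result` (or a numeric vector of p-values).
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  p <- if (is.numeric(scan)) scan else scan$p_value
  p <- sort(p[!is.na(p)])
  k <- length(p)
  df <- tibble::tibble(
    expected = -log10((seq_len(k) - 0.5) / k),
    observed = -log10(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda[GC] = %.3f", lambda_gc(p))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `scan_result` draws a Manhattan plot; `power_study_result` draws the
#' per-method power with standard-error bars.
#'
#' @param object The result object.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, ...) plot_manhattan(object, ...)

#' @rdname autoplot.scan_result
#' @method autoplot power_study_result
#' @export
autoplot.power_study_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$method, -.data$power), y = .data$power
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$power - .data$se,
                   ymax = .data$power + .data$se),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Power") +
    ggplot2::theme_minimal()
}
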