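#' Bar chart of burden reductions
#'
#' Grouped bars of the percent burden reduction per risk factor and sex,
#' faceted by scenario when the table covers several.
#'
#' @param object a `burden_tbl` from [apply_scenario()] or the `tables`
#'   element of a [run_tables()] report.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.burden_tbl <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
        x = .data$risk_factor, y = .data$gif_percent, fill = .data$sex)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "burden reduction (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (length(unique(d$scenario)) > 1) {
    p <- p + ggplot2::facet_wrap(~scenario)
  }
  p
}

#' @rdname autoplot.burden_tbl
#' @param tbl a `burden_tbl`.
#' @export
plot_burden_reduction <- function(tbl, ...) {
  autoplot.burden_tbl(tbl, ...)
}
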