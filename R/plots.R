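#' Plot a stability curve
#'
#' Mean outcome per region against the swept variable, with vertical
#' bars spanning +/- one between-subject SD — the standard way
#' time-stability of an outcome measure is displayed.
#'
#' @param curve A `stability_curve` (see [bpnd_vs_duration()]).
#' @param band Optional relative band drawn around each region's final
#'   value (e.g. 0.05); `NULL` for none.
#' @return A ggplot object.
#' @export
plot_stability <- function(curve, band = NULL) {
  stopifnot(inherits(curve, "stability_curve"))
  d <- tibble::as_tibble(curve)
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$sweep_value, y = .data$mean,
                    colour = .data$region)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = paste(attr(curve, "sweep"), "(min)"),
                  y = "outcome (mean ± SD)") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    finals <- d[!duplicated(d$region, fromLast = TRUE) &
                  d$sweep_value == ave(d$sweep_value, d$region, FUN = max), ]
    p <- p + ggplot2::geom_hline(
      yintercept = c(finals$mean * (1 - band), finals$mean * (1 + band)),
      linetype = "dotted", colour = "grey50"
    )
  }
  p
}

#' Plot a signed-R2 matrix
#'
#' Heatmap of the masked signed-R2 cells (below-threshold cells blank).
#'
#' @param m A [signed_r2_matrix()] result.
#' @return A ggplot object.
#' @export
plot_signed_r2 <- function(m) {
  stopifnot(inherits(m, "signed_r2_matrix"))
  d <- expand.grid(row = rownames(m$masked), col = colnames(m$masked),
                   stringsAsFactors = FALSE)
  d$value <- as.vector(m$masked)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1),
                                  na.value = "grey95",
                                  name = "signed R²") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
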