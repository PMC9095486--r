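# Diagnostic plots for spectra and match reports.

#' @export
autoplot.spectrum <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object), ggplot2::aes(.data$mz, .data$intensity)
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z", y = "Intensity")
}

#' @export
autoplot.match_report <- function(object, ...) {
  t <- tibble::as_tibble(object)
  t <- t[t$matched, ]
  ggplot2::ggplot(
    t,
    ggplot2::aes(.data$observed_mz, .data$intensity, colour = .data$series)
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$observed_mz, yend = 0)) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$ion),
      vjust = -0.4, size = 2.8, show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "m/z", y = "Intensity",
      title = sprintf("c/y assignment, coverage %.0f%%", 100 * coverage(object))
    )
}
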