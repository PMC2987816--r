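#' Plot a sliding-window scan profile
#'
#' Draws `-log10(p)` against the placement midpoint coordinate, one line
#' per scanned window size (the familiar scan-profile figure). Restrict
#' `w` to a few sizes for readability.
#'
#' @param object An `hsm_scan` tibble from [scan_block()].
#' @param w Window sizes to draw (default: all present).
#' @param stat `"lr"` or `"kw"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hsm_scan <- function(object, w = NULL, stat = c("lr", "kw"), ...) {
  stat <- match.arg(stat)
  pcol <- paste0(stat, "_p")
  if (!pcol %in% names(object)) stop(sprintf("scan lacks %s", pcol))
  d <- tibble::as_tibble(object)
  if (!is.null(w)) d <- d[d$w %in% w, ]
  d$neglog10p <- -log10(d[[pcol]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$midpoint, y = .data$neglog10p,
                                  colour = factor(.data$w))) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "placement midpoint (bp)",
      y = bquote(-log[10] ~ italic(p)),
      colour = "window size",
      title = sprintf("Sliding-window %s scan", toupper(stat))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a slope profile alongside significance
#'
#' @param profile Tibble from [slope_profile()].
#' @return A ggplot object showing the regression slope per placement.
#' @export
plot_slope_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$midpoint,
                                        y = .data$lr_slope)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "placement midpoint (bp)",
                  y = "regression slope per risk allele") +
    ggplot2::theme_minimal()
}

#' Plot DMR scan p-values
#'
#' @param object An `hsm_dmr` tibble from [dmr_scan()].
#' @param ... Unused.
#' @return A ggplot object: permutation p-value histogram with the
#'   q < 0.05 count in the subtitle.
#' @export
autoplot.hsm_dmr <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_perm)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey40") +
    ggplot2::labs(
      x = "permutation p-value", y = "ROIs",
      subtitle = sprintf("%d of %d ROIs at q < 0.05",
                         sum(d$q_value < 0.05), nrow(d))
    ) +
    ggplot2::theme_minimal()
}
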