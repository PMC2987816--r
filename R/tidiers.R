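#' Tidy a peak call
#'
#' @param x An `hsm_peak` from [peak_localise()].
#' @param ... Unused.
#' @return The per-window-size minima tibble (`w`, placement indices,
#'   coordinates, p-values): one row per scanned size.
#' @export
tidy.hsm_peak <- function(x, ...) x$per_w

#' One-row summary of a peak call
#'
#' @param x An `hsm_peak` from [peak_localise()].
#' @param ... Unused.
#' @return One-row tibble: `best_w`, `chrom`, `start`, `end`, `span_bp`,
#'   `idx_start`, `idx_end`, `best_lr_p`, `best_kw_p`.
#' @export
glance.hsm_peak <- function(x, ...) {
  tibble::tibble(
    best_w = x$best_w,
    chrom = x$best_interval$chrom,
    start = x$best_interval$start,
    end = x$best_interval$end,
    span_bp = region_width(x$best_interval),
    idx_start = x$best_idx[1],
    idx_end = x$best_idx[2],
    best_lr_p = x$best_lr_p,
    best_kw_p = x$best_kw_p
  )
}

#' One-row summary of a DMR scan
#'
#' @param x An `hsm_dmr` from [dmr_scan()].
#' @param ... Unused.
#' @return One-row tibble: `n_rois`, `n_perm`, `min_p_perm`,
#'   `n_q_below_05`.
#' @export
glance.hsm_dmr <- function(x, ...) {
  tibble::tibble(
    n_rois = nrow(x),
    n_perm = attr(x, "n_perm"),
    min_p_perm = min(x$p_perm),
    n_q_below_05 = sum(x$q_value < 0.05)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
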