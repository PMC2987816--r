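#' Fixed-width genomic window grid
#'
#' A `meth_grid` describes the tiling that methylation scores live on: a run
#' of `n_windows` consecutive windows of `window_size_bp` bases starting at a
#' 1-based genomic position, plus a per-window exclusion mask (repeat regions
#' or windows without usable probes). Window `k` (1-based, counting all
#' windows) spans `start + (k-1) * window_size_bp` to
#' `start + k * window_size_bp - 1` inclusive.
#'
#' All user-facing window indices in this package count *unmasked* windows
#' only; genomic coordinates are always reported alongside so masked gaps
#' stay visible.
#'
#' @param chrom Chromosome name (single string).
#' @param start 1-based inclusive genomic position of the first base of
#'   window 1.
#' @param n_windows Total number of windows on the grid (masked included).
#' @param window_size_bp Window width in bases (default 100).
#' @param mask Logical vector of length `n_windows`; `TRUE` marks an
#'   excluded window. Defaults to no exclusions.
#' @return An object of class `meth_grid`.
#' @examples
#' g <- meth_grid("chr16", start = 52362500, n_windows = 334)
#' window_to_coords(g, 161)
#' @export
meth_grid <- function(chrom, start, n_windows, window_size_bp = 100L,
                      mask = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.double(start)
  n_windows <- as.integer(n_windows)
  window_size_bp <- as.integer(window_size_bp)
  if (n_windows < 1L) stop("grid must have at least one window")
  if (window_size_bp < 1L) stop("window_size_bp must be a positive integer")
  if (is.null(mask)) mask <- rep(FALSE, n_windows)
  mask <- as.logical(mask)
  if (length(mask) != n_windows || anyNA(mask)) {
    stop("mask must be a logical vector of length n_windows with no NA")
  }
  if (all(mask)) stop("grid has no unmasked windows")
  structure(
    list(chrom = chrom, start = start, n_windows = n_windows,
         window_size_bp = window_size_bp, mask = mask),
    class = "meth_grid"
  )
}

#' @export
print.meth_grid <- function(x, ...) {
  cat(sprintf(
    "<meth_grid> %s:%s-%s  %d x %d bp windows (%d unmasked)\n",
    x$chrom, format(x$start, big.mark = ","),
    format(x$start + x$n_windows * x$window_size_bp - 1, big.mark = ","),
    x$n_windows, x$window_size_bp, n_unmasked(x)
  ))
  invisible(x)
}

#' Number of unmasked windows on a grid
#' @param grid A [meth_grid()].
#' @return Integer count.
#' @export
n_unmasked <- function(grid) {
  stopifnot(inherits(grid, "meth_grid"))
  sum(!grid$mask)
}

# genomic (all-window) indices of the unmasked windows, in order
unmasked_windows <- function(grid) which(!grid$mask)

#' Genomic span of unmasked windows
#'
#' Maps unmasked window indices to their genomic coordinates. Indices count
#' unmasked windows only, so index `k` is the k-th usable window, not the
#' k-th window on the grid.
#'
#' @param grid A [meth_grid()].
#' @param unmasked_index Integer vector of 1-based unmasked window indices.
#' @return A tibble with columns `unmasked_index`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @seealso [coords_to_window()] for the inverse mapping.
#' @export
window_to_coords <- function(grid, unmasked_index) {
  stopifnot(inherits(grid, "meth_grid"))
  unmasked_index <- as.integer(unmasked_index)
  nu <- n_unmasked(grid)
  if (length(unmasked_index) == 0L) stop("no index supplied")
  if (anyNA(unmasked_index) || any(unmasked_index < 1L) ||
      any(unmasked_index > nu)) {
    stop(sprintf("unmasked_index must lie in 1..%d", nu))
  }
  k <- unmasked_windows(grid)[unmasked_index]
  ws <- grid$window_size_bp
  tibble::tibble(
    unmasked_index = unmasked_index,
    chrom = grid$chrom,
    start = grid$start + (k - 1) * ws,
    end = grid$start + k * ws - 1
  )
}

#' Unmasked window index containing a genomic position
#'
#' Inverse of [window_to_coords()]: returns the 1-based unmasked window index
#' whose genomic span contains `pos`.
#'
#' @param grid A [meth_grid()].
#' @param pos Genomic position vector (1-based).
#' @return Integer vector of unmasked indices.
#' @export
coords_to_window <- function(grid, pos) {
  stopifnot(inherits(grid, "meth_grid"))
  pos <- as.double(pos)
  k <- floor((pos - grid$start) / grid$window_size_bp) + 1
  if (anyNA(k) || any(k < 1) || any(k > grid$n_windows)) {
    stop("position falls outside the grid")
  }
  k <- as.integer(k)
  if (any(grid$mask[k])) stop("position falls in a masked window")
  # rank of each genomic window among unmasked ones
  cumsum(!grid$mask)[k]
}

#' Define a genomic region
#'
#' Regions use 1-based inclusive coordinates throughout, matching the
#' tab-separated interfaces; BED input is converted on read.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param label Optional region label(s); defaults to `chrom:start-end`.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`.
#' @examples
#' region("chr16", 52378500, 52379399)  # the 900 bp narrow peak
#' @export
region <- function(chrom, start, end, label = NULL) {
  start <- as.double(start); end <- as.double(end)
  if (anyNA(start) || anyNA(end) || any(start > end)) {
    stop("regions need start <= end")
  }
  if (is.null(label)) label <- sprintf("%s:%.0f-%.0f", chrom, start, end)
  tibble::tibble(chrom = chrom, start = start, end = end, label = label)
}

#' Width of a region in bases
#' @param reg A one-or-more-row region tibble from [region()].
#' @return Numeric vector `end - start + 1`.
#' @export
region_width <- function(reg) reg$end - reg$start + 1

# Unmasked window indices (1-based, unmasked counting) of windows that lie
# entirely inside a region. Errors when the region is off-chromosome.
region_unmasked_indices <- function(grid, reg) {
  stopifnot(inherits(grid, "meth_grid"), nrow(reg) == 1L)
  if (!identical(reg$chrom, grid$chrom)) {
    stop(sprintf("region chromosome %s does not match grid chromosome %s",
                 reg$chrom, grid$chrom))
  }
  ws <- grid$window_size_bp
  k <- seq_len(grid$n_windows)
  w_start <- grid$start + (k - 1) * ws
  w_end <- w_start + ws - 1
  inside <- w_start >= reg$start & w_end <= reg$end & !grid$mask
  cumsum(!grid$mask)[which(inside)]
}
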