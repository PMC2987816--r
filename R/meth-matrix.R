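#' Sample-by-window methylation score matrix
#'
#' Holds absolute methylation scores (0 = unmethylated, 1 = fully
#' methylated) for a cohort on a shared [meth_grid()]. Scores are stored for
#' every grid window, masked ones included; analysis functions ignore masked
#' windows. Missing scores are allowed and propagate as `NA`.
#'
#' @param scores Numeric matrix, samples in rows, grid windows in columns.
#' @param grid A [meth_grid()] with `n_windows` equal to `ncol(scores)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(scores)`.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(scores, grid, sample_ids = rownames(scores)) {
  stopifnot(is.matrix(scores), inherits(grid, "meth_grid"))
  if (ncol(scores) != grid$n_windows) {
    stop(sprintf("scores has %d columns but the grid has %d windows",
                 ncol(scores), grid$n_windows))
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample_%02d", seq_len(nrow(scores)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(scores) || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and match the number of score rows")
  }
  bad <- which(!is.na(scores) & (scores < 0 | scores > 1))
  if (length(bad)) {
    stop(sprintf("%d methylation score(s) outside [0, 1]; first offender %g",
                 length(bad), scores[bad[1]]))
  }
  rownames(scores) <- sample_ids
  structure(list(scores = scores, grid = grid, sample_ids = sample_ids),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d samples x %d windows on ", nrow(x$scores),
              ncol(x$scores)))
  print(x$grid)
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$scores)

#' Long-format view of a methylation matrix
#'
#' @param x A [meth_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per sample/window pair: `sample_id`,
#'   `window` (all-window index), `unmasked_index` (`NA` for masked
#'   windows), `chrom`, `start`, `end`, `masked`, `score`.
#' @export
as_tibble.meth_matrix <- function(x, ...) {
  g <- x$grid
  k <- seq_len(g$n_windows)
  ws <- g$window_size_bp
  uidx <- ifelse(g$mask, NA_integer_, cumsum(!g$mask))
  win <- tibble::tibble(
    window = k,
    unmasked_index = as.integer(uidx),
    chrom = g$chrom,
    start = g$start + (k - 1) * ws,
    end = g$start + k * ws - 1,
    masked = g$mask
  )
  scores <- tibble::tibble(
    sample_id = rep(x$sample_ids, times = g$n_windows),
    window = rep(k, each = length(x$sample_ids)),
    score = as.vector(x$scores)
  )
  dplyr::arrange(
    dplyr::left_join(scores, win, by = "window"),
    .data$sample_id, .data$window
  )[, c("sample_id", "window", "unmasked_index", "chrom", "start", "end",
        "masked", "score")]
}
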