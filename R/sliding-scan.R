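# Shared geometry/load machinery for the sliding scan.
#
# Placements slide over contiguous *unmasked* window indices; the load of a
# placement of size w starting at region-relative unmasked index s is the
# mean score of its w windows. Loads for every placement of one size come
# from a running-sum update (cumulative sums along the window axis), not
# per-placement recomputation.

# region geometry: unmasked windows fully inside reg
scan_geometry <- function(matrix, reg) {
  reg <- tibble::as_tibble(reg)
  stopifnot(nrow(reg) == 1L)
  grid <- matrix$grid
  idx <- region_unmasked_indices(grid, reg)
  if (length(idx) == 0L) {
    stop(sprintf("region %s contains no unmasked windows", reg$label))
  }
  coords <- window_to_coords(grid, idx)
  S <- matrix$scores[, unmasked_windows(grid)[idx], drop = FALSE]
  list(reg = reg, idx = idx, coords = coords, S = S, W = length(idx),
       n = nrow(S))
}

# n x (W - w + 1) matrix of placement loads for one window size
placement_loads <- function(geom, w) {
  S <- geom$S
  W <- geom$W
  if (anyNA(S)) {
    Z <- ifelse(is.na(S), 0, S)
    cs <- cbind(0, t(apply(Z, 1, cumsum)))
    cc <- cbind(0, t(apply(!is.na(S), 1, cumsum)))
    sums <- cs[, (w + 1):(W + 1), drop = FALSE] -
      cs[, 1:(W - w + 1), drop = FALSE]
    cnts <- cc[, (w + 1):(W + 1), drop = FALSE] -
      cc[, 1:(W - w + 1), drop = FALSE]
    L <- sums / cnts
    L[cnts == 0] <- NA
    L
  } else {
    cs <- cbind(0, t(apply(S, 1, cumsum)))
    (cs[, (w + 1):(W + 1), drop = FALSE] -
       cs[, 1:(W - w + 1), drop = FALSE]) / w
  }
}

# vectorised per-placement OLS of load on dosage (optionally residualising
# both on an age covariate); identical to lm() per placement
placement_lr <- function(L, dosages, age = NULL) {
  n <- nrow(L)
  if (is.null(age)) {
    x <- dosages - mean(dosages)
    Yc <- sweep(L, 2, colMeans(L))
    df <- n - 2L
  } else {
    qA <- qr(cbind(1, age))
    x <- qr.resid(qA, dosages)
    Yc <- qr.resid(qA, L)
    df <- n - 3L
  }
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate genotype: constant dosage")
  sxy <- as.vector(crossprod(Yc, x))
  slope <- sxy / sxx
  sse <- pmax(colSums(Yc^2) - slope^2 * sxx, 0)
  se <- sqrt(sse / df / sxx)
  t <- slope / se
  tibble::tibble(lr_slope = slope, lr_t = t,
                 lr_p = 2 * stats::pt(-abs(t), df))
}

# vectorised per-placement Kruskal-Wallis across dosage groups
placement_kw <- function(L, dosages) {
  n <- nrow(L)
  R <- apply(L, 2, rank)
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  levs <- sort(unique(dosages))
  h <- 0
  for (g in levs) {
    sel <- dosages == g
    h <- h + colSums(R[sel, , drop = FALSE])^2 / sum(sel)
  }
  H <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- apply(L, 2, anyDuplicated) > 0
  if (any(ties)) {
    H[ties] <- H[ties] / apply(L[, ties, drop = FALSE], 2, kw_tie_divisor)
  }
  df <- length(levs) - 1L
  kw_p <- stats::pchisq(H, df, lower.tail = FALSE)
  kw_p[!is.finite(H)] <- 1  # all-tied columns: H = 0/0 convention
  H[!is.finite(H)] <- 0
  tibble::tibble(kw_stat = H, kw_p = kw_p)
}

#' Multi-scale sliding-window association scan of a block
#'
#' Slides windows of every requested size (in unmasked 100-bp windows,
#' stride one) across a region, computing the placement load (mean of its
#' window scores per sample) and testing its association with genotype
#' dosage by linear regression and/or Kruskal-Wallis at every placement.
#' At `w` equal to the region's unmasked window count the single placement
#' reproduces the block-level statistics of [block_scan()] exactly.
#'
#' Placements never silently span masked gaps: each row carries both the
#' region-relative unmasked index range and the genomic coordinates of its
#' first and last window, so gaps are visible. The plotting coordinate
#' `midpoint` is the mean of the placement's genomic start and end.
#'
#' @param matrix A [meth_matrix()].
#' @param dosages Per-sample dosage vector aligned to the matrix samples
#'   (see [dosage_vector()]).
#' @param reg One-row region tibble.
#' @param sizes `"all"` (1 up to the unmasked window count) or an integer
#'   vector of window sizes; sizes beyond the region are trimmed with a
#'   warning.
#' @param tests Character subset of `c("lr", "kw")`.
#' @param age Optional per-sample age covariate for the regression.
#' @param max_w Optional cap on the largest window size scanned.
#' @return A tibble of class `hsm_scan`, one row per (size, placement):
#'   `w`, `idx_start`, `idx_end`, `gstart`, `gend`, `midpoint`,
#'   `mean_0/1/2`, and the requested test columns.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, n_windows = 30,
#'                                      hsm_window_range = c(10, 12)), seed = 2)
#' reg <- region("chr16", 52362500, 52365499)
#' scan <- scan_block(cohort$methylation, cohort$truth$dosage, reg,
#'                    sizes = c(1, 3, 30))
#' peak_localise(scan)
#' @export
scan_block <- function(matrix, dosages, reg, sizes = "all",
                       tests = c("lr", "kw"), age = NULL, max_w = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  geom <- scan_geometry(matrix, reg)
  if (length(dosages) != geom$n) {
    stop("dosages must have one entry per sample")
  }
  if (anyNA(dosages)) stop("scan requires complete dosages")
  if (stats::var(dosages) == 0) stop("degenerate genotype: constant dosage")
  W <- geom$W
  if (identical(sizes, "all")) sizes <- seq_len(W)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L)) stop("window sizes must be positive")
  if (any(sizes > W)) {
    warning(sprintf("sizes beyond the %d unmasked windows trimmed", W))
    sizes <- sizes[sizes <= W]
  }
  if (!is.null(max_w)) sizes <- sizes[sizes <= max_w]
  if (length(sizes) == 0L) stop("no usable window sizes")

  grp <- lapply(0:2, function(g) dosages == g)
  w_starts <- geom$coords$start
  w_ends <- geom$coords$end

  out <- purrr::map(sizes, function(w) {
    L <- placement_loads(geom, w)
    P <- ncol(L)
    s <- seq_len(P)
    has_na <- anyNA(L)
    res <- tibble::tibble(
      w = w, idx_start = s, idx_end = s + w - 1L,
      gstart = w_starts[s], gend = w_ends[s + w - 1L]
    )
    res$midpoint <- (res$gstart + res$gend) / 2
    for (g in 0:2) {
      res[[paste0("mean_", g)]] <- if (any(grp[[g + 1]])) {
        colMeans(L[grp[[g + 1]], , drop = FALSE], na.rm = TRUE)
      } else NA_real_
    }
    if (has_na) {  # pairwise-complete fallback, placement by placement
      if ("lr" %in% tests) {
        lr <- purrr::map_dfr(s, function(j) {
          fit <- genotype_regression(L[, j], dosages, age = age)
          tibble::tibble(lr_slope = fit$lr_slope, lr_t = fit$lr_t,
                         lr_p = fit$lr_p)
        })
        res <- dplyr::bind_cols(res, lr)
      }
      if ("kw" %in% tests) {
        kw <- purrr::map_dfr(s, function(j) {
          k <- kruskal_wallis(L[, j], dosages)
          tibble::tibble(kw_stat = k$kw_stat, kw_p = k$kw_p)
        })
        res <- dplyr::bind_cols(res, kw)
      }
    } else {
      if ("lr" %in% tests) {
        res <- dplyr::bind_cols(res, placement_lr(L, dosages, age = age))
      }
      if ("kw" %in% tests) {
        res <- dplyr::bind_cols(res, placement_kw(L, dosages))
      }
    }
    res
  })
  out <- dplyr::bind_rows(out)
  structure(out, class = c("hsm_scan", class(out)),
            region = geom$reg, n_samples = geom$n, n_unmasked = W,
            tests = tests)
}

#' Localise the peak of a sliding-window scan
#'
#' Returns the placement with the globally smallest p-value across all
#' scanned sizes, with ties broken toward the smaller window size and then
#' the leftmost placement, plus the per-size minima so nesting of a narrow
#' peak inside a broader one can be inspected.
#'
#' @param scan An `hsm_scan` tibble from [scan_block()].
#' @param stat Test to rank by: `"lr"` (default) or `"kw"`.
#' @return An object of class `hsm_peak`: a list with `best_w`,
#'   `best_interval` (region tibble), `best_idx` (unmasked index range),
#'   `best_lr_p`, `best_kw_p`, and `per_w` (tibble of per-size minima).
#' @export
peak_localise <- function(scan, stat = c("lr", "kw")) {
  stat <- match.arg(stat)
  pcol <- paste0(stat, "_p")
  if (!pcol %in% names(scan)) {
    stop(sprintf("scan does not carry %s; rerun scan_block with that test", pcol))
  }
  p <- scan[[pcol]]
  if (all(is.na(p))) stop("all p-values missing")
  ord <- order(p, scan$w, scan$idx_start, na.last = TRUE)
  best <- scan[ord[1], ]
  reg_attr <- attr(scan, "region")
  per_w <- scan |>
    dplyr::group_by(.data$w) |>
    dplyr::slice_min(.data[[pcol]], n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(
    list(
      best_w = best$w,
      best_interval = region(
        if (!is.null(reg_attr)) reg_attr$chrom else NA_character_,
        best$gstart, best$gend, label = "scan_peak"),
      best_idx = c(best$idx_start, best$idx_end),
      best_lr_p = if ("lr_p" %in% names(best)) best$lr_p else NA_real_,
      best_kw_p = if ("kw_p" %in% names(best)) best$kw_p else NA_real_,
      stat = stat,
      per_w = per_w
    ),
    class = "hsm_peak"
  )
}

#' @export
print.hsm_peak <- function(x, ...) {
  cat(sprintf(
    "<hsm_peak> best w = %d (unmasked windows %d-%d, %s:%.0f-%.0f)\n  lr_p = %.3g  kw_p = %.3g\n",
    x$best_w, x$best_idx[1], x$best_idx[2], x$best_interval$chrom,
    x$best_interval$start, x$best_interval$end, x$best_lr_p, x$best_kw_p))
  invisible(x)
}

#' Regression slope profile at one window size
#'
#' Convenience wrapper around [scan_block()] returning the per-placement
#' regression slope under the rare-allele-dosage coding; regions where the
#' risk haplotype carries extra methylation show positive slope peaks
#' co-locating with the p-value peaks.
#'
#' @inheritParams scan_block
#' @param w Single window size.
#' @return A tibble: `idx_start`, `idx_end`, `midpoint`, `lr_slope`,
#'   `lr_p`.
#' @export
slope_profile <- function(matrix, dosages, reg, w, age = NULL) {
  scan <- scan_block(matrix, dosages, reg, sizes = w, tests = "lr",
                     age = age)
  tibble::as_tibble(scan)[, c("idx_start", "idx_end", "midpoint",
                              "lr_slope", "lr_p")]
}

#' Permutation p-values across a sliding scan
#'
#' Shuffles the genotype assignment once per permutation and applies the
#' same shuffle to every placement, preserving the spatial correlation of
#' the loads. `"pointwise"` mode returns the per-placement empirical
#' p-value (the convention used for a single placement of interest);
#' `"max_statistic"` mode compares each observed statistic against the
#' permutation distribution of the scan-wide maximum, giving family-wise
#' adjusted p-values across all scanned placements.
#'
#' @inheritParams scan_block
#' @param w_list Integer vector of window sizes to scan.
#' @param n_perm Number of genotype shuffles (at least 100).
#' @param seed Optional seed.
#' @param mode `"pointwise"` or `"max_statistic"`.
#' @param stat `"lr"` (|t| of the dosage slope) or `"kw"` (H).
#' @return A tibble: `w`, `idx_start`, `idx_end`, `stat_obs`, `p_perm`.
#' @export
scan_permutation <- function(matrix, dosages, reg, w_list, n_perm = 1000,
                             seed = NULL, mode = c("pointwise",
                                                   "max_statistic"),
                             stat = c("lr", "kw")) {
  mode <- match.arg(mode)
  stat <- match.arg(stat)
  if (n_perm < 100) stop("n_perm must be at least 100")
  geom <- scan_geometry(matrix, reg)
  if (anyNA(geom$S)) stop("scan_permutation requires complete scores")
  if (anyNA(dosages)) stop("scan_permutation requires complete dosages")
  n <- geom$n
  if (!is.null(seed)) set.seed(seed)

  w_list <- sort(unique(as.integer(w_list)))
  if (any(w_list > geom$W)) {
    warning("sizes beyond the unmasked window count trimmed")
    w_list <- w_list[w_list <= geom$W]
  }
  loads <- lapply(w_list, function(w) placement_loads(geom, w))
  L <- do.call(cbind, loads)
  meta <- tibble::tibble(
    w = rep(w_list, vapply(loads, ncol, 0L)),
    idx_start = unlist(lapply(loads, function(x) seq_len(ncol(x))))
  )
  meta$idx_end <- meta$idx_start + meta$w - 1L

  if (stat == "lr") {
    x_c <- dosages - mean(dosages)
    sxx <- sum(x_c^2)
    Yc <- sweep(L, 2, colMeans(L))
    syy <- colSums(Yc^2)
    t_of <- function(xmat) {  # placements x perms matrix of |t|
      sxy <- crossprod(Yc, xmat)
      r2 <- pmin(sweep(sxy^2, 1, sxx * syy, "/"), 1 - 1e-15)
      sqrt(r2 * (n - 2) / (1 - r2))
    }
    obs <- as.vector(t_of(cbind(x_c)))
    draw <- function(k) x_c[order(stats::runif(n))]
  } else {
    R <- apply(L, 2, rank)
    levs <- sort(unique(dosages))
    ng <- vapply(levs, function(g) sum(dosages == g), 0)
    tie_div <- apply(L, 2, kw_tie_divisor)
    t_of <- function(gmat) {  # gmat: n x perms of permuted dosages
      h <- 0
      for (i in seq_along(levs)) {
        h <- h + crossprod(R, gmat == levs[i])^2 / ng[i]
      }
      H <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
      H / tie_div
    }
    obs <- as.vector(t_of(cbind(dosages)))
    draw <- function(k) dosages[order(stats::runif(n))]
  }

  chunk <- 200L
  b <- numeric(nrow(meta))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    perm <- vapply(seq_len(m), draw, numeric(n))
    stat_perm <- t_of(perm)  # placements x m
    if (mode == "pointwise") {
      b <- b + rowSums(stat_perm >= obs - 1e-12)
    } else {
      mx <- apply(stat_perm, 2, max)
      b <- b + vapply(obs, function(o) sum(mx >= o - 1e-12), 0)
    }
    done <- done + m
  }
  meta$stat_obs <- obs
  meta$p_perm <- (b + 1) / (n_perm + 1)
  meta
}
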