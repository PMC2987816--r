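# Stage 3: empirical-Bayes differential-methylation caller.
#
# Case/control status is modelled by a logistic regression on the
# methylation values of the individual 100-bp proxies inside a region of
# interest. With roughly as many proxies as samples the coefficients are
# treated as draws from a common distribution with mean zero and variance
# sigma^2, and the null of no differential methylation becomes
# H0: sigma^2 = 0. The score test of that null is the quadratic form
#   Q = (y - ybar)' X X' (y - ybar) / nprox
# in the per-proxy-centered methylation matrix, assessed by permuting the
# sample labels.

#' Global score statistic for differential methylation in a ROI
#'
#' Computes the score statistic for `H0: sigma^2 = 0` in the
#' random-coefficient logistic model of case/control status on the ROI's
#' proxy methylation values: each proxy is centered across samples
#' (removing the intercept), and
#' `Q = sum_p (sum_s x_ps * (y_s - ybar))^2 / nprox`. `Q` is zero exactly
#' when every proxy is uncorrelated with the labels in-sample, and grows
#' with any coordinated association. Proxies are not variance-scaled by
#' default (`standardize = TRUE` divides each by its sample SD first).
#'
#' Proxies with some missing values are mean-imputed per proxy with a
#' warning; all-missing proxies are an error.
#'
#' @param M Numeric matrix, proxies in rows, samples in columns.
#' @param y Case/control labels (0/1 or logical), one per sample.
#' @param standardize Scale each proxy to unit variance before forming Q.
#' @return The statistic `Q` (non-negative scalar).
#' @export
global_test_statistic <- function(M, y, standardize = FALSE) {
  M <- as.matrix(M)
  y <- as.numeric(y)
  if (ncol(M) != length(y)) stop("M must have one column per sample")
  if (nrow(M) == 0L) stop("ROI has no proxies")
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("labels must contain both classes")
  }
  if (anyNA(y)) stop("labels must be complete")
  if (anyNA(M)) {
    if (any(rowSums(!is.na(M)) == 0L)) stop("ROI has an all-missing proxy")
    warning("missing proxy values mean-imputed per proxy")
    mu <- rowMeans(M, na.rm = TRUE)
    M[is.na(M)] <- mu[row(M)[is.na(M)]]
  }
  Xc <- M - rowMeans(M)
  if (standardize) {
    s <- sqrt(rowSums(Xc^2) / (ncol(M) - 1))
    s[s == 0] <- 1
    Xc <- Xc / s
  }
  z <- y - mean(y)
  sum(as.vector(Xc %*% z)^2) / nrow(M)
}

# permutation engine shared by roi_pvalue and dmr_scan: columns of
# perm_idx are sample orderings applied to the labels
roi_q_perms <- function(M, y, perm_idx, standardize = FALSE) {
  M <- as.matrix(M)
  if (anyNA(M)) {
    mu <- rowMeans(M, na.rm = TRUE)
    M[is.na(M)] <- mu[row(M)[is.na(M)]]
  }
  Xc <- M - rowMeans(M)
  if (standardize) {
    s <- sqrt(rowSums(Xc^2) / (ncol(M) - 1))
    s[s == 0] <- 1
    Xc <- Xc / s
  }
  z <- y - mean(y)
  Z <- apply(perm_idx, 2, function(i) z[i])
  colSums((Xc %*% Z)^2) / nrow(M)
}

#' Permutation and asymptotic p-values for one ROI
#'
#' The primary p-value permutes the sample labels (`p_perm =
#' (b + 1) / (n_perm + 1)` with `b` the number of permutations whose
#' statistic reaches the observed `Q`). An advisory asymptotic p-value is
#' also reported from a scaled chi-square moment-matched to the
#' permutation null of `Q`: its mean is computed in closed form from the
#' permutation moments of the quadratic form and its variance from the
#' permutation sample.
#'
#' @inheritParams global_test_statistic
#' @param n_perm Number of label permutations; values below 1000 warn
#'   (allowed for testing).
#' @param seed Optional integer seed.
#' @return One-row tibble: `Q`, `p_perm`, `p_asymptotic`, `n_perm`.
#' @export
roi_pvalue <- function(M, y, n_perm = 2000, seed = NULL,
                       standardize = FALSE) {
  if (n_perm < 1000) {
    warning("n_perm below 1000 is coarser than recommended for reported results")
  }
  if (!is.null(seed)) set.seed(seed)
  Q <- suppressWarnings(global_test_statistic(M, y, standardize))
  n <- length(y)
  perm_idx <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  Qp <- roi_q_perms(M, y, perm_idx, standardize)
  b <- sum(Qp >= Q - 1e-12)
  # closed-form permutation mean of Q: E[z_i z_j] = m2 (i = j),
  # -m2 / (n - 1) (i != j) for a permuted centered vector z
  M2 <- as.matrix(M)
  if (anyNA(M2)) {
    mu <- rowMeans(M2, na.rm = TRUE)
    M2[is.na(M2)] <- mu[row(M2)[is.na(M2)]]
  }
  Xc <- M2 - rowMeans(M2)
  if (standardize) {
    s <- sqrt(rowSums(Xc^2) / (n - 1)); s[s == 0] <- 1; Xc <- Xc / s
  }
  K <- crossprod(Xc) / nrow(M2)          # n x n kernel, Q = z' K z
  z <- y - mean(y)
  m2 <- mean(z^2)
  eq <- m2 * sum(diag(K)) - m2 / (n - 1) * (sum(K) - sum(diag(K)))
  vq <- stats::var(Qp)
  p_asym <- if (vq > 0 && eq > 0) {
    scale <- vq / (2 * eq)
    df <- 2 * eq^2 / vq
    stats::pchisq(Q / scale, df, lower.tail = FALSE)
  } else NA_real_
  tibble::tibble(Q = Q, p_perm = (b + 1) / (n_perm + 1),
                 p_asymptotic = p_asym, n_perm = n_perm)
}

#' Storey q-values at fixed lambda = 0.5
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > 0.5\} / (0.5 * m))` and converts p-values to
#' q-values by `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`,
#' which is monotone in p by construction.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values in \[0, 1\], same order as `p`.
#' @export
qvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  lambda <- 0.5
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- Inf
  for (i in seq_len(m)) {
    j <- ord[i]
    running <- min(running, pi0 * m * p[j] / (m - i + 1))
    q[j] <- running
  }
  pmin(q, 1)
}

#' Permutation-based false discovery rate
#'
#' Estimates, for each threshold `t`, `FDR(t)` as the average number of
#' null p-values at or below `t` per permutation divided by the observed
#' count at or below `t` (floored at one), capped at 1. Null p-values must
#' come from the same label shuffles applied to all ROIs jointly so that
#' between-ROI correlation is preserved.
#'
#' @param p_observed Observed p-values (length m).
#' @param p_null_matrix `n_perm x m` matrix of p-values from permuted
#'   labels.
#' @param thresholds Thresholds at which to evaluate; defaults to the
#'   observed p-values.
#' @return Tibble: `threshold`, `n_observed`, `mean_null`, `fdr`.
#' @export
permutation_fdr <- function(p_observed, p_null_matrix,
                            thresholds = NULL) {
  p_null_matrix <- as.matrix(p_null_matrix)
  if (ncol(p_null_matrix) != length(p_observed)) {
    stop("p_null_matrix must have one column per observed p-value")
  }
  if (is.null(thresholds)) thresholds <- sort(unique(p_observed))
  purrr::map_dfr(thresholds, function(t) {
    n_obs <- sum(p_observed <= t)
    mean_null <- mean(rowSums(p_null_matrix <= t))
    tibble::tibble(threshold = t, n_observed = n_obs,
                   mean_null = mean_null,
                   fdr = min(1, mean_null / max(1, n_obs)))
  })
}

#' Case/control DMR scan over regions of interest
#'
#' Runs the global test on every ROI using one shared permutation stream
#' (the same label shuffles applied to every ROI, preserving between-ROI
#' correlation), then attaches Storey q-values and the permutation FDR at
#' each ROI's observed p-value.
#'
#' @param matrix A [meth_matrix()].
#' @param metadata Metadata tibble with `sample_id` and `status` (1 =
#'   case).
#' @param rois Region tibble of ROIs (typically 500-4000 bp).
#' @param n_perm Label permutations shared across ROIs.
#' @param seed Optional integer seed.
#' @param standardize Passed to [global_test_statistic()].
#' @return Tibble of class `hsm_dmr`, one row per analysable ROI: region
#'   columns, `nprox`, `Q`, `p_perm`, `q_value`, `perm_fdr`. ROIs with no
#'   usable proxies are skipped with a warning.
#' @export
dmr_scan <- function(matrix, metadata, rois, n_perm = 2000, seed = NULL,
                     standardize = FALSE) {
  stopifnot(inherits(matrix, "meth_matrix"))
  rois <- tibble::as_tibble(rois)
  y <- metadata$status[match(matrix$sample_ids, metadata$sample_id)]
  if (anyNA(y)) stop("metadata must cover every sample in the matrix")
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)
  perm_idx <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))

  uw <- unmasked_windows(matrix$grid)
  rows <- purrr::map(seq_len(nrow(rois)), function(i) {
    reg <- rois[i, ]
    idx <- tryCatch(region_unmasked_indices(matrix$grid, reg),
                    error = function(e) integer(0))
    if (length(idx) == 0L) {
      warning(sprintf("ROI %s has no usable proxies, skipped", reg$label))
      return(NULL)
    }
    M <- t(matrix$scores[, uw[idx], drop = FALSE])
    ok <- rowSums(!is.na(M)) > 0L
    if (!any(ok)) {
      warning(sprintf("ROI %s has no usable proxies, skipped", reg$label))
      return(NULL)
    }
    M <- M[ok, , drop = FALSE]
    Q <- suppressWarnings(global_test_statistic(M, y, standardize))
    Qp <- roi_q_perms(M, y, perm_idx, standardize)
    b <- sum(Qp >= Q - 1e-12)
    # per-permutation null p-values: each permuted Q ranked against the
    # full permutation set
    p_null <- (n_perm - rank(Qp, ties.method = "min") + 1) / n_perm
    tibble::tibble(
      chrom = reg$chrom, start = reg$start, end = reg$end,
      label = reg$label, nprox = nrow(M), Q = Q,
      p_perm = (b + 1) / (n_perm + 1),
      p_null = list(p_null)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no analysable ROIs")
  out$q_value <- qvalues(out$p_perm)
  null_mat <- do.call(cbind, out$p_null)  # n_perm x m
  fdr <- permutation_fdr(out$p_perm, null_mat, thresholds = out$p_perm)
  out$perm_fdr <- fdr$fdr[match(out$p_perm, fdr$threshold)]
  out$p_null <- NULL
  structure(out, class = c("hsm_dmr", class(out)), n_perm = n_perm)
}
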