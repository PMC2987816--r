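#' Per-sample methylation load over a region
#'
#' The methylation load of a region is the per-sample arithmetic mean of
#' the 100-bp window scores over all unmasked windows lying fully inside
#' the region; missing scores are dropped per sample. Samples missing more
#' than half of the region's usable windows are flagged.
#'
#' @param matrix A [meth_matrix()].
#' @param reg A one-row region tibble ([region()]).
#' @return A tibble: `sample_id`, `load`, `n_windows_used`, `flagged`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 8, n_windows = 20,
#'                                      hsm_window_range = c(8, 10)), seed = 1)
#' methylation_load(cohort$methylation,
#'                  region("chr16", 52362500, 52364499))
#' @export
methylation_load <- function(matrix, reg) {
  stopifnot(inherits(matrix, "meth_matrix"))
  reg <- tibble::as_tibble(reg)
  if (nrow(reg) != 1L) stop("methylation_load takes a single region")
  idx <- region_unmasked_indices(matrix$grid, reg)
  if (length(idx) == 0L) {
    stop(sprintf("region %s contains no unmasked windows", reg$label))
  }
  sub <- matrix$scores[, unmasked_windows(matrix$grid)[idx], drop = FALSE]
  used <- rowSums(!is.na(sub))
  tibble::tibble(
    sample_id = matrix$sample_ids,
    load = unname(rowMeans(sub, na.rm = TRUE)),
    n_windows_used = unname(as.integer(used)),
    flagged = unname(used < length(idx) / 2)
  )
}

#' Kruskal-Wallis rank test of loads across genotype groups
#'
#' Wraps [stats::kruskal.test()] (midranks, tie correction, chi-square
#' reference with k - 1 df) with the package's conventions: pairs with a
#' missing value or group are dropped, and a degenerate input in which
#' every value is identical returns `H = 0, p = 1` rather than `NaN`.
#'
#' @param values Numeric vector (e.g. methylation loads).
#' @param groups Group labels (e.g. dosage 0/1/2); coerced to factor.
#' @return A one-row tibble: `kw_stat`, `kw_df`, `kw_p`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(kw_stat = 0, kw_df = nlevels(groups) - 1L,
                          kw_p = 1, n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(kw_stat = unname(kt$statistic),
                 kw_df = unname(kt$parameter),
                 kw_p = kt$p.value, n = length(values))
}

#' Linear regression of load on additive genotype dosage
#'
#' Ordinary least squares of the response on rare-allele dosage (0/1/2),
#' optionally adjusted for age. `lr_p` is the two-sided t-test p-value of
#' the dosage coefficient; the slope sign follows the rare-allele-count
#' coding, so a positive slope means higher methylation per rare (risk)
#' allele.
#'
#' @param values Numeric response.
#' @param dosages Additive dosage 0/1/2.
#' @param age Optional numeric covariate.
#' @return One-row tibble: `lr_slope`, `lr_se`, `lr_t`, `lr_p`, `age_p`
#'   (`NA` without a covariate), `n`.
#' @export
genotype_regression <- function(values, dosages, age = NULL) {
  keep <- !is.na(values) & !is.na(dosages)
  if (!is.null(age)) keep <- keep & !is.na(age)
  values <- values[keep]; dosages <- dosages[keep]
  if (!is.null(age)) age <- age[keep]
  n_min <- if (is.null(age)) 4L else 5L
  if (length(values) < n_min) {
    stop(sprintf("need at least %d complete observations", n_min))
  }
  if (stats::var(dosages) == 0) stop("degenerate genotype: constant dosage")
  fit <- if (is.null(age)) {
    stats::lm(values ~ dosages)
  } else {
    if (stats::var(age) == 0 || abs(stats::cor(dosages, age)) > 1 - 1e-12) {
      stop("collinear covariate")
    }
    stats::lm(values ~ dosages + age)
  }
  cf <- summary(fit)$coefficients
  tibble::tibble(
    lr_slope = cf["dosages", 1], lr_se = cf["dosages", 2],
    lr_t = cf["dosages", 3], lr_p = cf["dosages", 4],
    age_p = if (is.null(age)) NA_real_ else cf["age", 4],
    n = length(values)
  )
}

# --- fast statistic kernels used by the permutation machinery -------------

# tie-corrected Kruskal-Wallis H for a fixed rank vector and a matrix of
# group-label columns (one column per permutation); C is the tie divisor
kw_h_perm <- function(ranks, label_mat, levels, tie_divisor) {
  n <- length(ranks)
  h <- 0
  for (g in levels) {
    ind <- label_mat == g
    ng <- colSums(ind)
    sg <- colSums(ranks * ind)
    h <- h + sg^2 / ng
  }
  (12 / (n * (n + 1)) * h - 3 * (n + 1)) / tie_divisor
}

kw_tie_divisor <- function(values) {
  n <- length(values)
  t <- table(values)
  1 - sum(t^3 - t) / (n^3 - n)
}

# |t| of the dosage slope for fixed centered y and a matrix of permuted,
# centered dosage columns; sxx identical across permutations
lr_abs_t_perm <- function(y_c, x_mat_c, sxx, syy) {
  n <- length(y_c)
  sxy <- as.vector(crossprod(x_mat_c, y_c))
  r2 <- sxy^2 / (sxx * syy)
  r2 <- pmin(r2, 1 - 1e-15)
  sqrt(r2 * (n - 2) / (1 - r2))
}

#' Permutation empirical p-value for genotype association
#'
#' Retains the observed values and shuffles the genotype assignment
#' `n_perm` times (default 10,000), recomputing the chosen statistic each
#' time. The empirical p-value is `(b + 1) / (n_perm + 1)`, where `b`
#' counts permutations with statistic evidence at least as strong as
#' observed (Kruskal-Wallis: `H >= H_obs`; regression: `|t| >= |t_obs|`),
#' so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param values Numeric vector.
#' @param dosages Genotype dosages (used as group labels for `"kw"`, as an
#'   additive covariate for `"lr"`).
#' @param stat `"kw"` or `"lr"`.
#' @param n_perm Number of shuffles.
#' @param seed Optional integer seed for reproducibility.
#' @return One-row tibble: `p_perm`, `stat_obs`, `b`, `n_perm`.
#' @export
permutation_pvalue <- function(values, dosages, stat = c("lr", "kw"),
                               n_perm = 10000, seed = NULL) {
  stat <- match.arg(stat)
  if (n_perm < 100) warning("n_perm below 100 gives a very coarse p-value")
  keep <- !is.na(values) & !is.na(dosages)
  values <- values[keep]; dosages <- dosages[keep]
  n <- length(values)
  if (!is.null(seed)) set.seed(seed)

  if (stat == "kw") {
    groups <- factor(dosages)
    if (nlevels(droplevels(groups)) < 2L) stop("need two non-empty groups")
    ranks <- rank(values)
    tie_div <- kw_tie_divisor(values)
    if (tie_div == 0) stop("observed statistic is not finite (all values tied)")
    levs <- levels(droplevels(groups))
    obs <- kw_h_perm(ranks, matrix(as.character(groups), ncol = 1),
                     levs, tie_div)
    perm_mat <- replicate(n_perm, sample(as.character(groups)))
    stat_perm <- kw_h_perm(ranks, perm_mat, levs, tie_div)
  } else {
    if (stats::var(dosages) == 0) stop("degenerate genotype: constant dosage")
    y_c <- values - mean(values)
    x_c <- dosages - mean(dosages)
    sxx <- sum(x_c^2); syy <- sum(y_c^2)
    if (syy == 0) stop("observed statistic is not finite (constant values)")
    obs <- lr_abs_t_perm(y_c, matrix(x_c, ncol = 1), sxx, syy)
    perm_mat <- replicate(n_perm, sample(x_c))
    stat_perm <- lr_abs_t_perm(y_c, perm_mat, sxx, syy)
  }
  if (!is.finite(obs)) stop("observed statistic is not finite")
  b <- sum(stat_perm >= obs - 1e-12)
  tibble::tibble(p_perm = (b + 1) / (n_perm + 1), stat_obs = obs,
                 b = b, n_perm = n_perm)
}

#' Block-level genotype/methylation association scan
#'
#' Stage-1 analysis: for each region (LD block), computes the per-sample
#' methylation load, groups samples by the region's tag-SNP genotype, and
#' reports genotype-group means alongside Kruskal-Wallis, additive linear
#' regression (age-adjusted when metadata carries `age`), and permutation
#' empirical p-values. Samples are grouped by genotype only; case/control
#' status plays no role at this stage. P-values are reported uncorrected
#' together with a Bonferroni column across the supplied regions.
#'
#' @param matrix A [meth_matrix()].
#' @param genotypes Long genotype tibble ([read_genotypes()] format).
#' @param regions Region tibble; one row per block.
#' @param snp_map Tibble mapping `label` (region label) to `snp_id`. When
#'   `NULL` and a single SNP is present it is used for every region.
#' @param metadata Optional metadata tibble; its `age` column is used as a
#'   regression covariate when `covariate = "age"`.
#' @param covariate `NULL` or `"age"`.
#' @param n_perm Permutations per region (0 skips the permutation test).
#' @param perm_stat Statistic for the permutation p (`"lr"` or `"kw"`).
#' @param seed Optional seed for the permutation stream.
#' @return A tibble with one row per analysable region: region columns,
#'   `snp_id`, group means/counts `mean_0/1/2`, `n_0/1/2`, `kw_stat`,
#'   `kw_p`, `lr_slope`, `lr_p`, `age_p`, `perm_p`, `n_perm`,
#'   `p_bonferroni`. Regions whose tag SNP is absent are skipped with a
#'   warning.
#' @export
block_scan <- function(matrix, genotypes, regions, snp_map = NULL,
                       metadata = NULL, covariate = NULL,
                       n_perm = 10000, perm_stat = c("lr", "kw"),
                       seed = NULL) {
  perm_stat <- match.arg(perm_stat)
  regions <- tibble::as_tibble(regions)
  if (is.null(snp_map)) {
    snps <- unique(genotypes$snp_id)
    if (length(snps) != 1L) {
      stop("snp_map required when the genotype table holds several SNPs")
    }
    snp_map <- tibble::tibble(label = regions$label, snp_id = snps)
  }
  if (!is.null(seed)) set.seed(seed)
  age <- NULL
  if (identical(covariate, "age")) {
    if (is.null(metadata) || !"age" %in% names(metadata)) {
      stop("covariate = 'age' needs metadata with an age column")
    }
    age <- metadata$age[match(matrix$sample_ids, metadata$sample_id)]
  }

  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    snp <- snp_map$snp_id[match(reg$label, snp_map$label)]
    if (is.na(snp) || !snp %in% genotypes$snp_id) {
      warning(sprintf("region %s: tag SNP not found, skipped", reg$label))
      return(NULL)
    }
    load <- methylation_load(matrix, reg)
    dos <- dosage_vector(genotypes, snp, load$sample_id)
    grp_mean <- vapply(0:2, function(g) mean(load$load[dos %in% g]), 0)
    grp_n <- vapply(0:2, function(g) sum(dos %in% g & !is.na(load$load)), 0L)
    kw <- kruskal_wallis(load$load, dos)
    lr <- genotype_regression(load$load, dos, age = age)
    pp <- if (n_perm > 0) {
      permutation_pvalue(load$load, dos, stat = perm_stat, n_perm = n_perm)
    } else tibble::tibble(p_perm = NA_real_, n_perm = 0L)
    tibble::tibble(
      chrom = reg$chrom, start = reg$start, end = reg$end,
      label = reg$label, snp_id = snp,
      mean_0 = grp_mean[1], mean_1 = grp_mean[2], mean_2 = grp_mean[3],
      n_0 = grp_n[1], n_1 = grp_n[2], n_2 = grp_n[3],
      kw_stat = kw$kw_stat, kw_p = kw$kw_p,
      lr_slope = lr$lr_slope, lr_p = lr$lr_p, age_p = lr$age_p,
      perm_p = pp$p_perm, n_perm = pp$n_perm
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no analysable regions")
  out$p_bonferroni <- pmin(out$lr_p * nrow(out), 1)
  out
}
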