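small_cohort <- function(seed = 2, n = 24, W = 30, peak = c(10, 12),
                         effect = 0.15) {
  simulate_cohort(sim_config(n_samples = n, n_cases = n / 2, n_windows = W,
                             hsm_window_range = peak, effect_peak = effect,
                             effect_block = 0), seed = seed)
}

cohort_dosage <- function(cohort) {
  dosage_vector(cohort$genotypes, "rs8050136", cohort$methylation$sample_ids)
}

block_region_of <- function(cohort) {
  g <- cohort$methylation$grid
  region(g$chrom, g$start, g$start + g$n_windows * g$window_size_bp - 1,
         label = "blk")
}

test_that("the full-width placement reproduces block-level statistics exactly", {
  cohort <- small_cohort()
  d <- cohort_dosage(cohort)
  reg <- block_region_of(cohort)
  sc <- scan_block(cohort$methylation, d, reg, sizes = 30)
  expect_equal(nrow(sc), 1)
  load <- methylation_load(cohort$methylation, reg)
  kw <- kruskal_wallis(load$load, d)
  lr <- genotype_regression(load$load, d)
  expect_equal(sc$kw_stat, kw$kw_stat, tolerance = 1e-12)
  expect_equal(sc$kw_p, kw$kw_p, tolerance = 1e-12)
  expect_equal(sc$lr_slope, lr$lr_slope, tolerance = 1e-12)
  expect_equal(sc$lr_p, lr$lr_p, tolerance = 1e-12)
  expect_equal(sc$mean_0, mean(load$load[d == 0]), tolerance = 1e-12)
})

test_that("placement count, coordinates and running means are consistent", {
  cohort <- small_cohort(seed = 3)
  d <- cohort_dosage(cohort)
  reg <- block_region_of(cohort)
  sc <- scan_block(cohort$methylation, d, reg, sizes = c(1, 5), tests = "lr")
  expect_equal(sum(sc$w == 1), 30)
  expect_equal(sum(sc$w == 5), 26)
  expect_equal(sc$midpoint, (sc$gstart + sc$gend) / 2)
  # loads at w+1 are running means: (w+1) L_{w+1}(s) = w L_w(s) + x_{s+w}
  geom <- hsmscan:::scan_geometry(cohort$methylation, reg)
  L5 <- hsmscan:::placement_loads(geom, 5)
  L6 <- hsmscan:::placement_loads(geom, 6)
  expect_equal(6 * L6, 5 * L5[, 1:ncol(L6)] + geom$S[, 6:30],
               tolerance = 1e-12)
})

test_that("per-size scans agree with per-placement recomputation", {
  cohort <- small_cohort(seed = 4)
  d <- cohort_dosage(cohort)
  reg <- block_region_of(cohort)
  sc <- scan_block(cohort$methylation, d, reg, sizes = 4)
  geom <- hsmscan:::scan_geometry(cohort$methylation, reg)
  L <- hsmscan:::placement_loads(geom, 4)
  for (j in c(1, 9, 27)) {
    expect_equal(sc$lr_p[j], genotype_regression(L[, j], d)$lr_p,
                 tolerance = 1e-10)
    expect_equal(sc$kw_p[j], kruskal_wallis(L[, j], d)$kw_p,
                 tolerance = 1e-10)
  }
})

test_that("peak localisation recovers a strong synthetic effect", {
  cohort <- small_cohort(seed = 6, effect = 0.2)
  d <- cohort_dosage(cohort)
  sc <- scan_block(cohort$methylation, d, block_region_of(cohort),
                   sizes = "all", tests = "lr")
  pk <- peak_localise(sc)
  expect_true(pk$best_idx[1] <= 12 && pk$best_idx[2] >= 10)
  gl <- glance(pk)
  expect_equal(gl$span_bp, (pk$best_idx[2] - pk$best_idx[1] + 1) * 100)
  expect_equal(nrow(tidy(pk)), 30)
})

test_that("peak ties break toward smaller w then leftmost placement", {
  sc <- tibble::tibble(
    w = c(9, 5, 5), idx_start = c(2L, 7L, 3L), idx_end = c(10L, 11L, 7L),
    gstart = c(200, 700, 300), gend = c(1099, 1199, 799),
    midpoint = c(649.5, 949.5, 549.5),
    lr_p = c(1e-6, 1e-6, 1e-6), lr_slope = 0.1
  )
  class(sc) <- c("hsm_scan", class(sc))
  pk <- peak_localise(sc)
  expect_equal(pk$best_w, 5)
  expect_equal(pk$best_idx[1], 3)
})

test_that("slope profiles localise the effect and match block-level slope", {
  cohort <- small_cohort(seed = 8, effect = 0.2)
  d <- cohort_dosage(cohort)
  reg <- block_region_of(cohort)
  prof <- slope_profile(cohort$methylation, d, reg, w = 3)
  peak_rows <- prof$idx_start >= 8 & prof$idx_end <= 14
  expect_gt(max(prof$lr_slope[peak_rows]), max(prof$lr_slope[!peak_rows]))
  full <- slope_profile(cohort$methylation, d, reg, w = 30)
  load <- methylation_load(cohort$methylation, reg)
  expect_equal(full$lr_slope, genotype_regression(load$load, d)$lr_slope,
               tolerance = 1e-12)
  # null block: slopes centred on zero
  null <- simulate_null(sim_config(n_samples = 200, n_windows = 30,
                                   hsm_window_range = c(10, 12)), seed = 9)
  dn <- cohort_dosage(null)
  pn <- slope_profile(null$methylation, dn, block_region_of(null), w = 3)
  expect_lt(abs(mean(pn$lr_slope)), 0.01)
})

test_that("masked gaps stay visible in placement coordinates", {
  mask <- rep(FALSE, 30); mask[15] <- TRUE
  g <- meth_grid("chr1", 1, 30, 100, mask = mask)
  set.seed(10)
  m <- meth_matrix(matrix(runif(12 * 30), 12, 30), g)
  d <- rep(0:2, 4)
  sc <- scan_block(m, d, region("chr1", 1, 3000), sizes = 4, tests = "lr")
  spans <- sc$gend - sc$gstart + 1
  crossing <- sc$idx_start <= 14 & sc$idx_end >= 15
  expect_true(all(spans[crossing] == 500))
  expect_true(all(spans[!crossing] == 400))
})

test_that("oversized window requests are trimmed with a warning", {
  cohort <- small_cohort(seed = 11)
  d <- cohort_dosage(cohort)
  expect_warning(
    sc <- scan_block(cohort$methylation, d, block_region_of(cohort),
                     sizes = c(5, 99), tests = "lr"),
    "trimmed")
  expect_equal(unique(sc$w), 5)
})

test_that("scan permutations are seed-stable and detect the true placement", {
  cohort <- small_cohort(seed = 12, effect = 0.25)
  d <- cohort_dosage(cohort)
  reg <- block_region_of(cohort)
  a <- scan_permutation(cohort$methylation, d, reg, w_list = 3,
                        n_perm = 300, seed = 5)
  b <- scan_permutation(cohort$methylation, d, reg, w_list = 3,
                        n_perm = 300, seed = 5)
  expect_identical(a, b)
  true_row <- a$idx_start == 10
  expect_lte(min(a$p_perm[true_row]), 2 / 301)
  # family-wise mode is never more liberal than pointwise
  fw <- scan_permutation(cohort$methylation, d, reg, w_list = 3,
                         n_perm = 300, seed = 5, mode = "max_statistic")
  expect_true(all(fw$p_perm >= a$p_perm - 1e-12))
})

test_that("scan plots and accessors return the expected objects", {
  cohort <- small_cohort(seed = 13)
  d <- cohort_dosage(cohort)
  sc <- scan_block(cohort$methylation, d, block_region_of(cohort),
                   sizes = c(2, 4), tests = "lr")
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_slope_profile(
    slope_profile(cohort$methylation, d, block_region_of(cohort), 2)),
    "ggplot")
})
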