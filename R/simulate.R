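#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the study cohort this
#' package was designed around: 60 samples (30 cases, 30 controls), a tag
#' SNP at rare/risk-allele frequency 0.425 under Hardy-Weinberg, an LD
#' block of 334 usable 100-bp windows with per-window Gaussian noise of
#' SD 0.14 around a baseline of 0.50, a haplotype-phased methylation
#' elevation of 0.048 per risk allele confined to unmasked windows 161-169
#' (so the homozygote difference inside the peak is about 0.096, i.e. the
#' roughly 10% narrow-peak shift), a diffuse block-scale elevation of 0.017
#' per allele elsewhere (homozygote block-level shift about 0.034), and
#' ages drawn from Normal(37, 6.6) independent of genotype.
#'
#' The default grid anchors window 161 at chr16:52,378,500 so that, with no
#' masking, the effect interval carries the coordinates of the 900 bp
#' narrow peak (chr16:52,378,500-52,379,399).
#'
#' @param n_samples Cohort size.
#' @param n_cases Number of case-labelled samples (labels are independent
#'   of methylation unless `dmr_shift` is set).
#' @param maf Rare/risk-allele frequency of the tag SNP.
#' @param n_windows Number of usable (unmasked) windows on the block.
#' @param window_size_bp Window width in bases.
#' @param hsm_window_range Length-2 integer vector: unmasked-index interval
#'   carrying the peak effect.
#' @param effect_peak Mean methylation shift per risk allele inside
#'   `hsm_window_range`.
#' @param effect_block Mean shift per risk allele outside the peak.
#' @param baseline_mean Genotype-0 expected score.
#' @param noise_sd Per-window Gaussian noise SD (scores are clipped to
#'   \[0, 1\]).
#' @param age_mean,age_sd Age distribution (years).
#' @param age_beta Per-year age effect on every window (0 = age
#'   independent of methylation, the default).
#' @param mask_fraction Fraction of *additional* windows interleaved into
#'   the grid as masked repeat windows (0 = fully unmasked grid). The
#'   usable window count stays `n_windows`.
#' @param dmr_rois Optional region tibble; windows inside gain
#'   `dmr_shift` for case samples (for global-test power studies).
#' @param dmr_shift Case/control mean shift applied inside `dmr_rois`.
#' @param effect_profile Optional numeric vector of length `n_windows`
#'   giving the per-risk-allele shift per unmasked window; overrides
#'   `effect_peak`/`effect_block` geometry.
#' @param chrom,grid_start Grid placement.
#' @param snp_id Tag SNP name.
#' @param allele_common,allele_rare Tag SNP allele labels (rare = risk).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 60, n_cases = n_samples %/% 2,
                       maf = 0.425,
                       n_windows = 334, window_size_bp = 100,
                       hsm_window_range = c(161, 169),
                       effect_peak = 0.048, effect_block = 0.017,
                       baseline_mean = 0.50, noise_sd = 0.14,
                       age_mean = 37, age_sd = 6.6, age_beta = 0,
                       mask_fraction = 0,
                       dmr_rois = NULL, dmr_shift = 0,
                       effect_profile = NULL,
                       chrom = "chr16", grid_start = 52362500,
                       snp_id = "rs8050136",
                       allele_common = "C", allele_rare = "A") {
  if (n_cases > n_samples) stop("n_cases exceeds n_samples")
  if (maf <= 0 || maf >= 1) stop("maf must lie in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  hsm_window_range <- as.integer(hsm_window_range)
  if (length(hsm_window_range) != 2L || hsm_window_range[1] < 1L ||
      hsm_window_range[2] > n_windows ||
      hsm_window_range[1] > hsm_window_range[2]) {
    stop("hsm_window_range must be an increasing interval within 1..n_windows")
  }
  if (mask_fraction < 0 || mask_fraction >= 1) {
    stop("mask_fraction must lie in [0, 1)")
  }
  if (!is.null(effect_profile) && length(effect_profile) != n_windows) {
    stop("effect_profile must have one entry per usable window")
  }
  structure(as.list(environment()), class = "sim_config")
}

# per-unmasked-window per-risk-allele effect implied by a config
config_effect_profile <- function(config) {
  if (!is.null(config$effect_profile)) return(config$effect_profile)
  eff <- rep(config$effect_block, config$n_windows)
  eff[config$hsm_window_range[1]:config$hsm_window_range[2]] <-
    config$effect_peak
  eff
}

# grid with n_windows usable windows; mask_fraction interleaves masked ones
# outside the peak so the peak stays genomically contiguous
config_grid <- function(config, rng_ready = FALSE) {
  nw <- config$n_windows
  if (config$mask_fraction == 0) {
    return(meth_grid(config$chrom, config$grid_start, nw,
                     config$window_size_bp))
  }
  n_masked <- round(config$mask_fraction / (1 - config$mask_fraction) * nw)
  peak <- config$hsm_window_range
  # gap slot k (0..nw) sits after the k-th unmasked window; slots strictly
  # inside the peak are excluded so the peak stays genomically contiguous
  eligible <- setdiff(0:nw, peak[1]:(peak[2] - 1L))
  cnt <- tabulate(sample(eligible, n_masked, replace = TRUE) + 1L,
                  nbins = nw + 1L)
  mask <- logical(0)
  for (k in 0:nw) {
    mask <- c(mask, rep(TRUE, cnt[k + 1L]), if (k < nw) FALSE)
  }
  meth_grid(config$chrom, config$grid_start, length(mask),
            config$window_size_bp, mask = mask)
}

#' Simulate a cohort with haplotype-driven methylation structure
#'
#' Draws tag-SNP genotypes from Hardy-Weinberg proportions, ages from a
#' normal distribution independent of genotype, case/control labels
#' independent of methylation (unless a DMR shift is configured), and
#' per-window scores as
#' `clip(baseline + dosage * effect(window) + N(0, noise_sd^2), 0, 1)`.
#' Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with elements `methylation` ([meth_matrix()]),
#'   `genotypes` (long tibble as in [read_genotypes()]), `metadata`
#'   (tibble: `sample_id`, `status`, `age`, `sex`), and `truth` (list:
#'   per-sample `dosage`, the `effect_region` tibble, `effect_windows`
#'   unmasked-index range, and `expected_means`, a 3 x n_windows matrix of
#'   expected scores by genotype).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 12, n_windows = 20,
#'                                      hsm_window_range = c(8, 10)),
#'                           seed = 1)
#' cohort$methylation
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_samples
  maf <- config$maf
  eff <- config_effect_profile(config)

  exp_means <- rbind(config$baseline_mean + 0 * eff,
                     config$baseline_mean + 1 * eff,
                     config$baseline_mean + 2 * eff)
  rownames(exp_means) <- c("dosage0", "dosage1", "dosage2")
  out_by <- pmax(exp_means - 1, -exp_means, 0)
  if (any(out_by > 3 * config$noise_sd)) {
    warning("configured effects push expected means outside (0, 1) by more ",
            "than 3 noise SDs; clipping will distort them")
  }

  sample_ids <- sprintf("S%03d", seq_len(n))
  dosage <- sample(0:2, n, replace = TRUE,
                   prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  status <- sample(rep(c(1L, 0L), c(config$n_cases, n - config$n_cases)))

  grid <- config_grid(config)
  uw <- unmasked_windows(grid)
  scores <- matrix(NA_real_, n, grid$n_windows)
  mu <- outer(dosage, eff) + config$baseline_mean +
    config$age_beta * (age - config$age_mean)
  noise <- matrix(stats::rnorm(n * length(uw), 0, config$noise_sd),
                  n, length(uw))
  scores[, uw] <- mu + noise
  if (!is.null(config$dmr_rois) && config$dmr_shift != 0) {
    for (r in seq_len(nrow(config$dmr_rois))) {
      idx <- region_unmasked_indices(grid, config$dmr_rois[r, ])
      scores[status == 1L, uw[idx]] <-
        scores[status == 1L, uw[idx]] + config$dmr_shift
    }
  }
  scores <- pmin(pmax(scores, 0), 1)

  peak <- config$hsm_window_range
  peak_coords <- window_to_coords(grid, peak[1]:peak[2])
  effect_region <- region(grid$chrom, min(peak_coords$start),
                          max(peak_coords$end), label = "hsm_peak")

  genotypes <- tibble::tibble(
    sample_id = sample_ids, snp_id = config$snp_id, dosage = dosage,
    allele_common = config$allele_common, allele_rare = config$allele_rare
  )
  metadata <- tibble::tibble(sample_id = sample_ids, status = status,
                             age = age, sex = "F")
  list(
    methylation = meth_matrix(scores, grid, sample_ids),
    genotypes = genotypes,
    metadata = metadata,
    truth = list(dosage = stats::setNames(dosage, sample_ids),
                 effect_region = effect_region,
                 effect_windows = peak,
                 effect_profile = eff,
                 expected_means = exp_means)
  )
}

#' Simulate a null cohort (all effects zero)
#'
#' Identical to [simulate_cohort()] with the genotype, age, DMR and peak
#' effects all forced to zero; used for type-I-error calibration.
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort()].
#' @export
simulate_null <- function(config = sim_config(), seed = NULL) {
  config$effect_peak <- 0
  config$effect_block <- 0
  config$effect_profile <- NULL
  config$dmr_shift <- 0
  config$age_beta <- 0
  simulate_cohort(config, seed = seed)
}

#' Simulate a bisulphite-pyrosequencing validation table
#'
#' Generates per-sample percent methylation at individual CpG sites, some
#' of which exist only on one allele of a local CpG-creating SNP. At an
#' SNP-dependent site the bisulphite read reports the fraction of
#' methylatable alleles, so percent is about `100 * local_dosage / 2` plus
#' assay noise; constitutive sites sit at their own baseline independent of
#' genotype. The local CpG-SNP genotype equals the tag-SNP genotype except
#' in `n_discordant` injected samples, emulating imperfect LD between the
#' tag SNP and the CpG-SNP.
#'
#' @param config A [sim_config()] (supplies cohort size and tag-SNP MAF).
#' @param sites Tibble with columns `site` (position or id),
#'   `snp_dependent` (logical) and optionally `base_percent` (constitutive
#'   level, default 95).
#' @param n_discordant Number of samples whose local genotype is made to
#'   disagree with the tag genotype (drawn among risk-allele carriers).
#' @param noise_sd_percent Assay noise SD in percentage points.
#' @param seed Integer seed.
#' @return A list: `pyro`, a tibble (`sample_id`, `site`, `percent`,
#'   `snp_dependent`, `local_dosage`, `tag_dosage`), and
#'   `discordant_samples`, the injected sample ids.
#' @export
simulate_pyro_table <- function(config = sim_config(), sites,
                                n_discordant = 0, noise_sd_percent = 2,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(sites))
  if (!all(c("site", "snp_dependent") %in% names(sites))) {
    stop("sites needs columns site and snp_dependent")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  maf <- config$maf
  tag <- sample(0:2, n, replace = TRUE,
                prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
  local <- tag
  disc <- character(0)
  if (n_discordant > 0) {
    carriers <- which(tag >= 1)
    if (length(carriers) < n_discordant) {
      stop("not enough risk-allele carriers to inject discordance")
    }
    pick <- sample(carriers, n_discordant)
    local[pick] <- pmax(tag[pick] - sample(1:2, n_discordant, replace = TRUE),
                        0)
    # guarantee an actual disagreement even when tag - 2 clips at 0 = tag
    local[pick] <- ifelse(local[pick] == tag[pick], tag[pick] - 1L,
                          local[pick])
    disc <- sample_ids[pick]
  }
  base <- if ("base_percent" %in% names(sites)) sites$base_percent else
    rep(95, nrow(sites))
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(j) {
    mu <- if (sites$snp_dependent[j]) 100 * local / 2 else rep(base[j], n)
    tibble::tibble(
      sample_id = sample_ids,
      site = sites$site[j],
      percent = pmin(pmax(mu + stats::rnorm(n, 0, noise_sd_percent), 0), 100),
      snp_dependent = sites$snp_dependent[j],
      local_dosage = local,
      tag_dosage = tag
    )
  })
  list(pyro = rows, discordant_samples = disc)
}
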