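revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), ""))
}

test_that("the narrow-peak SNP trio classifies as one YpG and two CpR", {
  calls <- classify_cpg_snp(narrow_peak_snps())
  expect_equal(calls$motif_class, c("YpG", "CpR", "CpR"))
  expect_equal(calls$cpg_allele, c("C", "G", "G"))
})

test_that("ancestral polarity gives two gains and one loss for the trio", {
  calls <- ancestral_polarity(classify_cpg_snp(narrow_peak_snps()))
  expect_equal(calls$effect_vs_ancestral, c("loss", "gain", "gain"))
  # missing ancestral base
  na_calls <- ancestral_polarity(classify_cpg_snp(narrow_peak_snps()),
                                 ancestral = c(NA, "A", "A"))
  expect_equal(na_calls$effect_vs_ancestral[1], "unknown")
  # ancestral base not among the alleles
  expect_warning(
    bad <- ancestral_polarity(classify_cpg_snp(narrow_peak_snps()),
                              ancestral = c("G", "A", "A")),
    "not among")
  expect_equal(bad$effect_vs_ancestral[1], "unknown")
})

test_that("SNPs without CpG potential or with N flanks are handled", {
  snps <- tibble::tibble(
    snp_id = c("flatAG", "flatCT", "n_flank"),
    pos = c(100, 200, 300),
    left_flank = c("TTTTT", "AAAAA", "AAAAN"),
    allele_a = c("A", "C", "A"),
    allele_b = c("G", "T", "G"),
    right_flank = c("TTTTT", "AAAAA", "TTTTT"))
  calls <- classify_cpg_snp(snps)
  expect_equal(calls$motif_class, rep("none", 3))
  expect_true(calls$flank_unknown[3])
  pol <- ancestral_polarity(calls, ancestral = c("A", "C", "A"))
  expect_equal(pol$effect_vs_ancestral, c("none", "none", "unknown"))
})

test_that("classification is strand-invariant (CpG palindromy)", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    lf <- paste(sample(bases, 5, replace = TRUE), collapse = "")
    rf <- paste(sample(bases, 5, replace = TRUE), collapse = "")
    al <- sample(bases, 2)
    fwd <- tibble::tibble(snp_id = "x", pos = 1, left_flank = lf,
                          allele_a = al[1], allele_b = al[2],
                          right_flank = rf)
    rev <- tibble::tibble(snp_id = "x", pos = 1,
                          left_flank = revcomp(rf),
                          allele_a = revcomp(al[1]),
                          allele_b = revcomp(al[2]),
                          right_flank = revcomp(lf))
    cf <- classify_cpg_snp(fwd)
    cr <- classify_cpg_snp(rev)
    expect_equal(cf$motif_class != "none", cr$motif_class != "none")
    if (cf$motif_class != "none") {
      expect_equal(cr$cpg_allele, revcomp(cf$cpg_allele))
    }
  }
})

test_that("proximity clustering matches the worked pair and the brute force", {
  pair <- tibble::tibble(pos = c(52379116, 52379191))  # exactly 75 bp apart
  expect_equal(cluster_cpg_snps(pair, 75)$cluster, c(1L, 1L))
  expect_equal(cluster_cpg_snps(tibble::tibble(pos = c(100, 300)), 75)$cluster,
               c(1L, 2L))
  chain <- tibble::tibble(pos = c(0, 75, 150))
  expect_equal(cluster_cpg_snps(chain, 75)$cluster, rep(1L, 3))
  set.seed(23)
  for (i in 1:10) {
    pos <- sort(sample(1:2000, sample(2:50, 1)))
    got <- cluster_cpg_snps(tibble::tibble(pos = pos), 75)
    want <- oracle_single_linkage(pos, 75)
    expect_equal(got$cluster, want[order(pos)])
  }
})

test_that("haplotype CpG capability counts gains and losses", {
  snps <- narrow_peak_snps()
  calls <- classify_cpg_snp(snps)
  risk <- dplyr::mutate(calls, ref_allele = snps$ref_allele,
                        hap_allele = snps$risk_allele)
  alt <- dplyr::mutate(calls, ref_allele = snps$ref_allele,
                       hap_allele = snps$ref_allele)
  cap_risk <- haplotype_cpg_capability(7, risk, label = "risk")
  cap_alt <- haplotype_cpg_capability(7, alt, label = "reference")
  expect_equal(cap_risk$total, 10)
  expect_equal(cap_alt$total, 7)
  expect_equal(cap_risk$gains, 3)
  # capability identity between two haplotypes
  expect_equal(cap_risk$total - cap_alt$total,
               (cap_risk$gains - cap_alt$gains) -
                 (cap_risk$losses - cap_alt$losses))
  # gain/loss cancellation
  mixed <- tibble::tibble(cpg_allele = c("C", "G"), ref_allele = c("C", "A"),
                          hap_allele = c("T", "G"))
  expect_equal(haplotype_cpg_capability(5, mixed)$total, 5)
  # invalid haplotype allele
  bad <- dplyr::mutate(risk, hap_allele = "T")
  expect_error(haplotype_cpg_capability(7, bad[2, ]), "not one of")
})

test_that("LD metrics match hand computation and behave at the extremes", {
  a <- rep(c(1, 0), each = 4)
  expect_equal(ld_metrics(a, a)[, c("d_prime", "r2")],
               tibble::tibble(d_prime = 1, r2 = 1))
  # counts AB:3 Ab:1 aB:1 ab:3 -> D = 1/8, D' = 0.5, r2 = 0.25
  hapA <- c(1, 1, 1, 1, 0, 0, 0, 0)
  hapB <- c(1, 1, 1, 0, 1, 0, 0, 0)
  m <- ld_metrics(hapA, hapB)
  expect_equal(m$d, 1 / 8)
  expect_equal(m$d_prime, 0.5)
  expect_equal(m$r2, 0.25)
  set.seed(25)
  ind <- ld_metrics(rbinom(10000, 1, 0.4), rbinom(10000, 1, 0.6))
  expect_lt(ind$r2, 0.01)
  expect_error(ld_metrics(rep(1, 8), hapB), "monomorphic")
  # 0 <= r2 <= D' <= 1 across random draws
  for (i in 1:20) {
    x <- rbinom(40, 1, runif(1, 0.2, 0.8))
    y <- rbinom(40, 1, runif(1, 0.2, 0.8))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    m <- ld_metrics(x, y)
    expect_true(m$r2 >= -1e-12 && m$r2 <= m$d_prime + 1e-12 &&
                  m$d_prime <= 1 + 1e-12)
  }
})

test_that("site summaries stratify by genotype and flag ASM only when real", {
  sites <- tibble::tibble(site = c(1, 2), snp_dependent = c(TRUE, FALSE),
                          base_percent = c(NA, 95))
  noiseless <- simulate_pyro_table(sim_config(n_samples = 80, n_cases = 40),
                                   sites, noise_sd_percent = 1e-9, seed = 27)
  summ <- site_genotype_methylation(noiseless$pyro)
  dep <- summ[summ$site == 1, ]
  expect_equal(c(dep$mean_0, dep$mean_1, dep$mean_2), c(0, 50, 100),
               tolerance = 1e-6)
  expect_true(is.na(dep$asm_flag))
  cons <- summ[summ$site == 2, ]
  expect_false(cons$asm_flag)

  # constitutive site with a genuine +20-point shift in dosage-2 carriers
  hits <- 0
  for (s in 1:10) {
    tab <- simulate_pyro_table(sim_config(n_samples = 80, n_cases = 40),
                               tibble::tibble(site = 9, snp_dependent = FALSE,
                                              base_percent = 60),
                               noise_sd_percent = 5, seed = 100 + s)$pyro
    tab$percent <- pmin(tab$percent + 20 * (tab$tag_dosage == 2), 100)
    hits <- hits + site_genotype_methylation(tab)$asm_flag
  }
  expect_gte(hits, 9)
})

test_that("re-stratification recovers concordant-only means", {
  sites <- tibble::tibble(site = 52379190, snp_dependent = TRUE)
  sim <- simulate_pyro_table(sim_config(n_samples = 80, n_cases = 40), sites,
                             n_discordant = 2, noise_sd_percent = 2,
                             seed = 29)
  rs <- restratify_by_local_genotype(sim$pyro)
  expect_setequal(rs$discordant$sample_id, sim$discordant_samples)
  conc <- sim$pyro[!sim$pyro$sample_id %in% sim$discordant_samples, ]
  expect_equal(rs$means$mean_2, mean(conc$percent[conc$tag_dosage == 2]))
  # concordant-only dosage-2 mean sits near 100%
  expect_gt(rs$means$mean_2, 95)
  # fully concordant table: nothing listed, means unchanged
  sim0 <- simulate_pyro_table(sim_config(n_samples = 40, n_cases = 20), sites,
                              seed = 31)
  rs0 <- restratify_by_local_genotype(sim0$pyro)
  expect_equal(nrow(rs0$discordant), 0)
  expect_equal(rs0$means$mean_1,
               mean(sim0$pyro$percent[sim0$pyro$tag_dosage == 1]))
  # all discordant: degenerate with warning
  all_disc <- sim0$pyro
  all_disc$local_dosage <- all_disc$tag_dosage + 1
  expect_warning(rs_bad <- restratify_by_local_genotype(all_disc),
                 "all samples discordant")
  expect_true(all(is.nan(unlist(rs_bad$means[, c("mean_0", "mean_1",
                                                 "mean_2")]))))
})

test_that("composition mining reports the three fractions", {
  trio <- mine_cpg_snp_stats(narrow_peak_snps())
  expect_equal(trio$frac_cpg_site, 1)
  expect_equal(trio$frac_gain, 2 / 3)
  expect_equal(trio$frac_gain_clustered, 2 / 3)  # the 75 bp CpR pair

  none <- tibble::tibble(snp_id = "x", pos = 1, left_flank = "TT",
                         allele_a = "A", allele_b = "C", right_flank = "TT",
                         ancestral = "A")
  z <- mine_cpg_snp_stats(none)
  expect_equal(unlist(z[, -1]), c(frac_cpg_site = 0, frac_gain = 0,
                                  frac_gain_clustered = 0))

  # constructed composition: 100 SNPs, 40 CpG-class, 10 gains, 2 clustered
  gains <- tibble::tibble(
    snp_id = sprintf("g%02d", 1:10), pos = c(1000, 1075, seq(5000, 40000, 5000)),
    left_flank = "AAC", allele_a = "A", allele_b = "G", right_flank = "TTT",
    ancestral = "A")
  losses <- tibble::tibble(
    snp_id = sprintf("l%02d", 1:30), pos = seq(100000, 129000, 1000),
    left_flank = "AAC", allele_a = "A", allele_b = "G", right_flank = "TTT",
    ancestral = "G")
  flat <- tibble::tibble(
    snp_id = sprintf("f%02d", 1:60), pos = seq(200000, 259000, 1000),
    left_flank = "AAT", allele_a = "A", allele_b = "C", right_flank = "TTT",
    ancestral = "A")
  mix <- rbind(gains, losses, flat)
  stats <- mine_cpg_snp_stats(mix)
  expect_equal(stats$frac_cpg_site, 0.40)
  expect_equal(stats$frac_gain, 0.10)
  expect_equal(stats$frac_gain_clustered, 0.02)
  expect_error(mine_cpg_snp_stats(mix[0, ]), "empty")
})
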