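# Stage 4: CpG-creating/abrogating SNP genetics.
#
# A SNP can create or destroy a CpG dinucleotide in two ways: a YpG SNP
# (alleles C/T immediately before a G) or a CpR SNP (alleles A/G
# immediately after a C). Because CpG is palindromic, a YpG on one strand
# is a CpR on the other, so checking both patterns on the supplied strand
# makes the call strand-invariant.

#' Classify SNPs as CpG-creating/abrogating (YpG or CpR)
#'
#' For each SNP context, calls `YpG` when the alleles are \{C, T\} and the
#' base immediately 3' is G (the C allele completes a CpG), `CpR` when the
#' alleles are \{A, G\} and the base immediately 5' is C (the G allele
#' completes a CpG), and `none` otherwise. When the adjacent flank base
#' that would decide a call is `N`, the motif is reported as `none` with
#' `cpg_allele = NA` and downstream polarity `unknown`.
#'
#' @param snps Tibble of SNP contexts with columns `snp_id`, `pos` (or
#'   `position`), `left_flank`, `right_flank`, `allele_a`, `allele_b`
#'   (see [read_snp_contexts()]).
#' @return The input tibble with added columns `motif_class`
#'   (`"YpG"`/`"CpR"`/`"none"`), `cpg_allele` (allele under which the CpG
#'   exists, `NA` when none) and `flank_unknown` (adjacent base was `N`).
#' @examples
#' snps <- tibble::tibble(
#'   snp_id = c("rs7206629", "rs7202116", "rs7202296"),
#'   pos = c(52378914, 52379116, 52379191),
#'   left_flank = c("TTGGT", "TAAAC", "AAGCC"),
#'   allele_a = c("T", "A", "A"), allele_b = c("C", "G", "G"),
#'   right_flank = c("GAAGT", "TCTTT", "ATAAA"))
#' classify_cpg_snp(snps)
#' @export
classify_cpg_snp <- function(snps) {
  snps <- tibble::as_tibble(snps)
  need <- c("snp_id", "left_flank", "right_flank", "allele_a", "allele_b")
  if (!all(need %in% names(snps))) {
    stop(sprintf("need columns %s", paste(need, collapse = ", ")))
  }
  if (any(nchar(snps$left_flank) < 1L) || any(nchar(snps$right_flank) < 1L)) {
    stop("flanks must be at least 1 bp")
  }
  left_base <- toupper(substr(snps$left_flank, nchar(snps$left_flank),
                              nchar(snps$left_flank)))
  right_base <- toupper(substr(snps$right_flank, 1, 1))
  a <- toupper(snps$allele_a)
  b <- toupper(snps$allele_b)
  ct <- (a == "C" & b == "T") | (a == "T" & b == "C")
  ag <- (a == "A" & b == "G") | (a == "G" & b == "A")
  ypg <- ct & right_base == "G"
  cpr <- ag & left_base == "C"
  unknown <- (ct & right_base == "N") | (ag & left_base == "N")
  snps$motif_class <- ifelse(ypg, "YpG", ifelse(cpr, "CpR", "none"))
  snps$cpg_allele <- ifelse(ypg, "C", ifelse(cpr, "G", NA_character_))
  snps$flank_unknown <- unknown
  snps
}

#' Polarise CpG-SNP calls against the ancestral base
#'
#' A classified CpG-SNP is a `gain` of methylatability when the ancestral
#' base differs from the CpG-forming allele (the derived allele created
#' the CpG) and a `loss` when the ancestral base is the CpG-forming allele
#' (the derived allele destroyed it). SNPs without a CpG motif are
#' `none`; a missing ancestral base, an `N`-obscured flank, or an
#' ancestral base not among the two alleles (tri-allelic or misannotated,
#' warned) give `unknown`.
#'
#' @param calls Output of [classify_cpg_snp()]; must carry an `ancestral`
#'   column unless `ancestral` is supplied.
#' @param ancestral Optional vector of ancestral bases overriding the
#'   column.
#' @return `calls` with an added `effect_vs_ancestral` column
#'   (`"gain"`/`"loss"`/`"none"`/`"unknown"`).
#' @export
ancestral_polarity <- function(calls, ancestral = NULL) {
  calls <- tibble::as_tibble(calls)
  if (!"motif_class" %in% names(calls)) {
    stop("calls must come from classify_cpg_snp")
  }
  anc <- toupper(if (is.null(ancestral)) calls$ancestral else ancestral)
  anc[anc %in% c("", ".", "N")] <- NA
  a <- toupper(calls$allele_a); b <- toupper(calls$allele_b)
  bad <- !is.na(anc) & anc != a & anc != b
  if (any(bad)) {
    warning(sprintf("%d SNP(s) with ancestral base not among the alleles; set to unknown",
                    sum(bad)))
  }
  eff <- dplyr::case_when(
    calls$motif_class == "none" & calls$flank_unknown ~ "unknown",
    calls$motif_class == "none" ~ "none",
    is.na(anc) | bad ~ "unknown",
    anc == calls$cpg_allele ~ "loss",
    TRUE ~ "gain"
  )
  calls$effect_vs_ancestral <- eff
  calls
}

#' Reconcile ancestral bases from several outgroup species
#'
#' Helper for multi-species ancestral assignment: returns the shared base
#' when all outgroups agree and `NA` (unknown) otherwise.
#'
#' @param ... Character vectors of outgroup bases, one per species.
#' @return Character vector of unanimous bases, `NA` where species
#'   disagree or any base is missing.
#' @export
reconcile_ancestral <- function(...) {
  mat <- cbind(...)
  apply(mat, 1, function(r) {
    r <- toupper(r)
    if (anyNA(r) || length(unique(r)) != 1L) NA_character_ else r[1]
  })
}

#' Cluster CpG-SNPs by genomic proximity
#'
#' Single-linkage clustering on genomic distance: two calls join the same
#' cluster when they lie within `max_dist_bp` of each other directly or
#' through a chain of intermediate calls. The default threshold of 75 bp
#' is inclusive (distance exactly 75 clusters together).
#'
#' @param calls Tibble with a `pos` column (one chromosome at a time).
#' @param max_dist_bp Linking distance in bases.
#' @return `calls` sorted by position with an added integer `cluster`
#'   column.
#' @export
cluster_cpg_snps <- function(calls, max_dist_bp = 75) {
  calls <- tibble::as_tibble(calls)
  if (!"pos" %in% names(calls)) stop("calls need a pos column")
  calls <- dplyr::arrange(calls, .data$pos)
  if (nrow(calls) == 0L) {
    calls$cluster <- integer(0)
    return(calls)
  }
  gap <- c(FALSE, diff(calls$pos) > max_dist_bp)
  calls$cluster <- cumsum(gap) + 1L
  calls
}

#' CpG capability of a haplotype
#'
#' Counts the CpG sites a haplotype can methylate in a region: the
#' reference CpG count, plus gains (the haplotype carries the CpG-forming
#' allele at a site where the reference base does not form the CpG), minus
#' losses (the reference forms the CpG but the haplotype allele destroys
#' it).
#'
#' @param reference_cpg_count CpG sites in the reference sequence of the
#'   region.
#' @param phased_calls Tibble with columns `cpg_allele`, `ref_allele`,
#'   `hap_allele` (the allele this haplotype bears), and optionally
#'   `allele_a`/`allele_b` for validation.
#' @param label Haplotype label.
#' @return One-row tibble: `label`, `reference_cpg_count`, `gains`,
#'   `losses`, `total`.
#' @export
haplotype_cpg_capability <- function(reference_cpg_count, phased_calls,
                                     label = "haplotype") {
  pc <- tibble::as_tibble(phased_calls)
  need <- c("cpg_allele", "ref_allele", "hap_allele")
  if (!all(need %in% names(pc))) {
    stop(sprintf("phased_calls needs columns %s", paste(need, collapse = ", ")))
  }
  if (all(c("allele_a", "allele_b") %in% names(pc))) {
    ok <- pc$hap_allele == pc$allele_a | pc$hap_allele == pc$allele_b
    if (any(!ok)) {
      stop(sprintf("haplotype allele '%s' is not one of the SNP's alleles",
                   pc$hap_allele[which(!ok)[1]]))
    }
  }
  gains <- sum(pc$hap_allele == pc$cpg_allele &
                 pc$ref_allele != pc$cpg_allele, na.rm = TRUE)
  losses <- sum(pc$ref_allele == pc$cpg_allele &
                  pc$hap_allele != pc$cpg_allele, na.rm = TRUE)
  total <- reference_cpg_count + gains - losses
  if (total < 0) stop("negative CpG capability: check reference count")
  tibble::tibble(label = label, reference_cpg_count = reference_cpg_count,
                 gains = gains, losses = losses, total = total)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Standard two-locus LD from phased binary haplotype vectors:
#' `D = pAB - pA * pB`, `D' = |D| / Dmax`, and
#' `r^2 = D^2 / (pA qA pB qB)`.
#'
#' @param hapA,hapB Vectors over the same phased haplotypes; coerced to
#'   binary by matching the first level/unique value.
#' @return One-row tibble: `d`, `d_prime`, `r2`, `n_hap`.
#' @export
ld_metrics <- function(hapA, hapB) {
  to_bin <- function(h) {
    u <- sort(unique(h))
    if (length(u) != 2L) stop("monomorphic or multi-allelic locus")
    as.numeric(h == u[2])
  }
  a <- to_bin(hapA); b <- to_bin(hapB)
  if (length(a) != length(b)) stop("haplotype vectors must align")
  pa <- mean(a); pb <- mean(b)
  pab <- mean(a * b)
  d <- pab - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  tibble::tibble(d = d, d_prime = if (dmax == 0) NA_real_ else abs(d) / dmax,
                 r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)),
                 n_hap = length(a))
}

#' Genome-scale CpG-SNP composition summary
#'
#' Classifies and polarises a table of SNP contexts and reports three
#' fractions over the supplied table: SNPs with CpG potential under either
#' allele, ancestral gains of methylatability, and gain SNPs lying within
#' `max_dist_bp` of another gain.
#'
#' @param snps SNP context tibble (columns as [classify_cpg_snp()] plus
#'   `pos` and `ancestral`).
#' @param max_dist_bp Clustering distance for the third fraction.
#' @return One-row tibble: `n_snps`, `frac_cpg_site`, `frac_gain`,
#'   `frac_gain_clustered`.
#' @export
mine_cpg_snp_stats <- function(snps, max_dist_bp = 75) {
  snps <- tibble::as_tibble(snps)
  if (nrow(snps) == 0L) stop("empty SNP table")
  calls <- ancestral_polarity(classify_cpg_snp(snps))
  n <- nrow(calls)
  gains <- calls[calls$effect_vs_ancestral == "gain", ]
  n_clustered <- 0L
  if (nrow(gains) > 1L) {
    cl <- cluster_cpg_snps(gains, max_dist_bp)
    sizes <- table(cl$cluster)
    n_clustered <- sum(cl$cluster %in% as.integer(names(sizes)[sizes > 1]))
  }
  tibble::tibble(
    n_snps = n,
    frac_cpg_site = mean(calls$motif_class != "none"),
    frac_gain = nrow(gains) / n,
    frac_gain_clustered = n_clustered / n
  )
}

#' Genotype-stratified site methylation summary
#'
#' Summarises a bisulphite-pyrosequencing percent-methylation table by
#' tag-SNP genotype group per CpG site. For sites that are not
#' SNP-dependent, a Kruskal-Wallis test across genotype groups flags
#' allele-specific methylation (`asm_flag`) at significance `alpha`
#' (default 0.01, uncorrected; set `bonferroni = TRUE` to adjust across
#' sites).
#'
#' @param pyro Tibble with columns `sample_id`, `site`, `percent` and
#'   `tag_dosage` (or supply `genotypes`/`snp` to look dosages up).
#' @param site_snp_dependence Optional tibble (`site`, `snp_dependent`);
#'   taken from a `snp_dependent` column of `pyro` when present.
#' @param alpha ASM flag significance level.
#' @param bonferroni Adjust `alpha` across tested sites.
#' @return Tibble, one row per site: `site`, `snp_dependent`,
#'   `mean_0/1/2`, `n_0/1/2`, `kw_p`, `asm_flag` (`NA` for SNP-dependent
#'   sites or when fewer than two genotype groups are represented).
#' @export
site_genotype_methylation <- function(pyro, site_snp_dependence = NULL,
                                      alpha = 0.01, bonferroni = FALSE) {
  pyro <- tibble::as_tibble(pyro)
  need <- c("sample_id", "site", "percent", "tag_dosage")
  if (!all(need %in% names(pyro))) {
    stop(sprintf("pyro needs columns %s", paste(need, collapse = ", ")))
  }
  if (any(pyro$percent < 0 | pyro$percent > 100, na.rm = TRUE)) {
    stop("percent methylation must lie in [0, 100]")
  }
  dep <- if (!is.null(site_snp_dependence)) {
    site_snp_dependence
  } else if ("snp_dependent" %in% names(pyro)) {
    dplyr::distinct(pyro[, c("site", "snp_dependent")])
  } else {
    stop("supply site_snp_dependence or a snp_dependent column")
  }
  sites <- unique(pyro$site)
  n_tested <- sum(!dep$snp_dependent[match(sites, dep$site)])
  a_eff <- if (bonferroni && n_tested > 0) alpha / n_tested else alpha
  purrr::map_dfr(sites, function(s) {
    d <- pyro[pyro$site == s, ]
    sd_flag <- dep$snp_dependent[match(s, dep$site)]
    means <- vapply(0:2, function(g) mean(d$percent[d$tag_dosage %in% g]), 0)
    ns <- vapply(0:2, function(g) sum(d$tag_dosage %in% g), 0L)
    groups_present <- sum(ns > 0)
    kw_p <- NA_real_
    asm <- NA
    if (groups_present >= 2L) {
      kw_p <- kruskal_wallis(d$percent, d$tag_dosage)$kw_p
      if (!isTRUE(sd_flag)) asm <- kw_p < a_eff
    }
    tibble::tibble(site = s, snp_dependent = sd_flag,
                   mean_0 = means[1], mean_1 = means[2], mean_2 = means[3],
                   n_0 = ns[1], n_1 = ns[2], n_2 = ns[3],
                   kw_p = kw_p, asm_flag = asm)
  })
}

#' Re-stratify a pyrosequencing table by local CpG-SNP genotype
#'
#' When the tag SNP and the CpG-creating SNP are in imperfect LD, some
#' samples carry a tag genotype that misstates their local CpG
#' capability. This lists every sample whose local CpG-SNP dosage
#' disagrees with the tag dosage and recomputes the per-tag-genotype site
#' means on the concordant samples only.
#'
#' @param pyro Tibble with columns `sample_id`, `site`, `percent`,
#'   `tag_dosage`, `local_dosage` (e.g. from [simulate_pyro_table()], or a
#'   real table with the CpG-SNP genotype read off the pyrosequencing
#'   trace).
#' @return A list: `discordant` (tibble of `sample_id`, `tag_dosage`,
#'   `local_dosage`), and `means` (per site and tag genotype, concordant
#'   samples only; `NaN` with a warning when a group empties).
#' @export
restratify_by_local_genotype <- function(pyro) {
  pyro <- tibble::as_tibble(pyro)
  need <- c("sample_id", "site", "percent", "tag_dosage", "local_dosage")
  if (!all(need %in% names(pyro))) {
    stop(sprintf("pyro needs columns %s", paste(need, collapse = ", ")))
  }
  per_sample <- dplyr::distinct(pyro[, c("sample_id", "tag_dosage",
                                         "local_dosage")])
  discordant <- per_sample[per_sample$local_dosage != per_sample$tag_dosage, ]
  conc <- pyro[!pyro$sample_id %in% discordant$sample_id, ]
  if (nrow(conc) == 0L) {
    warning("all samples discordant; re-stratified means are empty")
  }
  means <- purrr::map_dfr(unique(pyro$site), function(s) {
    d <- conc[conc$site == s, ]
    tibble::tibble(
      site = s,
      mean_0 = mean(d$percent[d$tag_dosage %in% 0]),
      mean_1 = mean(d$percent[d$tag_dosage %in% 1]),
      mean_2 = mean(d$percent[d$tag_dosage %in% 2]),
      n_concordant = nrow(d)
    )
  })
  list(discordant = discordant, means = means)
}
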