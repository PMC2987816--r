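---
title: "Haplotype-specific methylation scanning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-specific methylation scanning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hsmscan` analyses cohort methylation data delivered as absolute
methylation scores on a fixed 100-bp window grid — the output level of
Bayesian MeDIP-chip deconvolution — together with SNP genotypes, and asks
whether methylation tracks the genetic haplotype. This vignette documents
the statistical models, the tunable parameters, the synthetic-data
generator used to validate every stage, and the numerical and design
choices behind the implementation.

## Data model

All coordinates are 1-based inclusive, matching the tab-separated
interfaces; BED/BEDGRAPH ingestion converts from 0-based half-open on
read. A `meth_grid` carries the tiling (chromosome, start, window size,
window count) and a per-window exclusion mask for repeat regions or
windows without usable probes. How masked windows are identified is a
property of the upstream platform, so the mask is an *input*, never a
computation. Every user-facing window index counts unmasked windows only
— this is the only convention under which a 60-window region can span
7.7 kb of genome — and all outputs carry genomic coordinates alongside
indices so masked gaps stay visible.

Scores live in [0, 1] (0 = unmethylated, 1 = fully methylated); missing
scores propagate as `NA` and each operation states its own
missing-data policy (loads drop missing windows per sample and flag
samples missing more than half a region; the global test mean-imputes
within proxy with a warning).

## Stage 1 — block-level association

The *methylation load* of a region is the per-sample arithmetic mean of
its unmasked window scores. Samples are grouped by the dosage of the
region's tag SNP (0/1/2 copies of the rare allele; the rare allele is the
risk allele in the motivating locus but results always carry allele
labels), and the load is tested against dosage three ways:

* **Kruskal–Wallis** across the three genotype groups (midranks, tie
  correction, chi-square reference with $k-1$ df) — sensitive to any
  ordering, not just additive effects. Delegated to
  `stats::kruskal.test()`; the degenerate all-tied input returns
  $H = 0, p = 1$ by documented convention.
* **Linear regression** of load on additive dosage, optionally adjusted
  for age (`stats::lm()`); the reported `lr_p` is the two-sided t-test of
  the dosage coefficient. Age enters because methylation drifts with age
  at some loci; in the motivating data it was not a significant
  confounder, and the generator therefore simulates age independent of
  methylation by default (an `age_beta` switch adds a real age effect for
  covariate testing).
* **Permutation**: genotype labels are shuffled (default 10,000 times)
  with the scores held fixed, and the empirical p-value is
  $(b+1)/(n_{perm}+1)$ where $b$ counts shuffles with evidence at least
  as strong as observed ($H \ge H_{obs}$, or $|t| \ge |t_{obs}|$). This
  estimator never returns zero: the attainable floor is
  $1/(n_{perm}+1)$, i.e. $10^{-4}$ at 10,000 shuffles, and the package
  reports that floor explicitly rather than claiming smaller values.

Across blocks, p-values are reported uncorrected plus a Bonferroni
column; no FDR at this stage.

## Stage 2 — multi-scale sliding-window scan

To localise a signal inside a block, windows of every size $w$ from 1 to
the block's unmasked window count slide across it with stride one. The
placement load is the mean of its $w$ window scores, computed by a
running-sum (cumulative sum) update — the $O(W^2)$ placement grid is
affordable precisely because each size reuses the same cumulative sums
(334 usable windows give 55,945 placements; a full LR scan of one cohort
of 60 samples runs in about a second). Each placement is tested exactly
as in stage 1, and plotted at the midpoint of its genomic span.

Placements slide over *unmasked indices*, so a placement may bridge a
masked gap; its genomic start/end always expose this. `peak_localise()`
returns the global minimum-p placement across all (size, placement)
pairs, breaking exact ties toward the smaller size and then the leftmost
placement, plus per-size minima so the characteristic nesting of a
narrow peak at the downstream edge of a broader one can be inspected.

Scan-wide permutation supports two modes: `pointwise` (the per-placement
convention used for a single placement of interest) and `max_statistic`,
which compares each placement against the permutation distribution of
the scan-wide maximum and thereby controls the family-wise error across
the whole $W^2/2$ grid. One genotype shuffle is applied to *all*
placements per permutation, preserving the spatial correlation of the
loads. The max-statistic mode is an extension beyond the pointwise
convention of the motivating analysis and is labelled as such.

## Stage 3 — empirical-Bayes DMR calling

Case/control differential methylation is tested per region of interest
(ROI, typically 500–4000 bp) from the individual 100-bp *proxies* inside
it rather than their average. Status $P_s$ is modelled by logistic
regression on the proxy values $m_{ps}$; with about as many proxies as
samples, the per-proxy coefficients are treated as draws from a common
distribution with mean zero and variance $\sigma^2$, and the null of no
differential methylation becomes $H_0: \sigma^2 = 0$. The score test of
that null is the quadratic form

$$Q = (y - \bar y)^\top X X^\top (y - \bar y)\, /\, n_{prox},$$

with $X$ the per-proxy-centered proxy-by-sample matrix — the canonical
score statistic for this random-coefficient formulation. Centering
removes the intercept; proxies are *not* variance-scaled by default (the
proxy values themselves carry the signal), with a `standardize` switch.
$Q = 0$ exactly when every proxy is uncorrelated with the labels
in-sample.

Significance is assessed primarily by label permutation
($(b+1)/(n_{perm}+1)$, shared shuffles across all ROIs). An advisory
asymptotic p-value moment-matches a scaled chi-square: the permutation
mean of $Q$ has a short closed form (for a permuted centered label
vector, $E[z_iz_j]$ is $m_2$ on the diagonal and $-m_2/(n-1)$ off it),
while the variance is matched from the permutation sample — at $n = 60$
the permutation p is the one to report, so the asymptotic value is
advisory only.

Multiplicity is handled two ways: Storey q-values with $\pi_0$ estimated
at fixed $\lambda = 0.5$ (one fewer degree of freedom than a
$\lambda$-smoother, fully reproducible), and a permutation FDR,
$\widehat{FDR}(t) = \overline{\#\{p_{null} \le t\}} / \max(1, \#\{p_{obs}
\le t\})$, from the same shared shuffles.

## Stage 4 — CpG-creating SNP genetics

A SNP creates or abrogates a CpG in exactly two motif classes: **YpG**
(alleles C/T immediately 5' of a G) and **CpR** (alleles A/G immediately
3' of a C). CpG is palindromic, so a YpG on one strand is a CpR on the
other; checking both classes on the supplied strand makes the call
strand-invariant, which a property test verifies on random reverse
complements. An `N` at the deciding flank base yields an explicit
`unknown` rather than a call.

Polarity against the ancestral base classifies each motif SNP as a
*gain* of methylatability (the derived allele created the CpG) or a
*loss*; a multi-species helper accepts outgroup bases and requires
unanimity, else `unknown`. In-phase clusters are found by single-linkage
at a distance threshold read as *inclusive* ≤ 75 bp — the worked pair of
CpR gains in the motivating locus sits exactly 75 bp apart — and
haplotype CpG capability is reference count + gains − losses, which for
the risk haplotype of the motivating locus gives 10 methylatable sites
against 7 on the alternate haplotype.

Pyrosequencing re-analysis treats an SNP-dependent site's percent
methylation as the bisulphite-read C fraction, so a non-CpG allele reads
as unmethylated and percent tracks local CpG-allele dosage (≈0/50/100).
Sites that are not SNP-dependent are tested for allele-specific
methylation by Kruskal–Wallis across tag genotype groups at α = 0.01,
uncorrected by default because validation tables are small (a Bonferroni
switch exists). When tag and CpG-SNP are in imperfect LD,
`restratify_by_local_genotype()` lists tag/local-discordant samples and
recomputes group means on concordant samples only.

The genome-scale miner reports, over a supplied SNP table: the fraction
with CpG potential under *either* allele (the documented reading of
"occurs at a CpG site"), the fraction of ancestral gains, and the
fraction of gains within 75 bp of another gain. Chromosome-scale
reproduction requires an external dbSNP extract and is out of scope.

## The synthetic cohort generator

`sim_config()` defaults *are* the study conditions the package is
validated under, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_samples`, `n_cases` | 60, 30 | all-female cohort, half cases |
| `maf` | 0.425 | tag-SNP rare/risk allele frequency (Hardy–Weinberg) |
| `n_windows` | 334 | usable 100-bp windows in the block |
| `hsm_window_range` | 161–169 | unmasked-index interval carrying the peak effect |
| `effect_peak` | 0.048 | per-risk-allele shift inside the peak (homozygote difference ≈ 0.096) |
| `effect_block` | 0.017 | diffuse per-allele shift elsewhere (block-level homozygote difference ≈ 0.034) |
| `baseline_mean` | 0.50 | genotype-0 expected score |
| `noise_sd` | 0.14 | per-window Gaussian noise SD |
| `age_mean`, `age_sd` | 37, 6.6 | ages, independent of genotype and methylation |

Scores are `clip(baseline + dosage × effect(window) + N(0, noise_sd²),
0, 1)`. Noise is Gaussian because only an empirical SD is known for the
motivating data; clipping bias is negligible at a 0.5 baseline (a config
warning fires if expected means leave (0, 1) by more than 3 SDs).
Effects enter additively per risk allele, matching the near-additive
genotype means observed at this locus. The default grid anchors unmasked
window 161 at chr16:52,378,500 so the effect interval carries the
coordinates of the 900 bp narrow peak. Case/control labels are
independent of methylation unless a `dmr_shift` is configured on
designated ROIs; `simulate_null()` zeroes every effect for calibration.
An `effect_profile` override supports stepped geometries (e.g. a broad
moderate elevation with a narrow strong peak at its downstream edge).

What the generator does **not** emulate: MeDIP enrichment, fragment-size
effects, probe intensities, or the upstream Bayesian inference — scores
are generated at the deconvolved-output level. Windows are independent
by default; the real data's spatial autocorrelation is unknown, so
passing calibration here does not certify behaviour under strong
autocorrelation (loads of wide placements would be noisier than the
independent-window model implies, making the block tests *less*
powerful, not anticonservative under permutation). The pyrosequencing
simulator draws discordant samples among all risk-allele carriers, a
slight generalisation of the observed discordance pattern.

## Numerical choices and problem sizes

* Permutation p-values use $(b+1)/(n_{perm}+1)$ with a $10^{-12}$
  absolute tolerance on the ≥ comparison so floating-point noise cannot
  flip a tie.
* The vectorised scan computes the dosage-slope t from cross-products
  after centering (or after residualising both sides on age via QR);
  it agrees with `lm()` per placement to ~10⁻¹⁵ relative error, and the
  full-width placement reproduces block-level statistics to 1e-12.
* Exact ties in peak localisation break toward smaller window size, then
  leftmost placement.
* Test-suite problem sizes, chosen to keep the default run to a few
  minutes while leaving Monte-Carlo margins: 1,000 null cohorts for
  type-I calibration (rejection within [0.03, 0.07] at α = 0.05 for all
  four tests, 200 shuffles per permutation p), a 200-ROI null DMR scan
  at 500 shuffles, and 100 replicates of the full 334-window multi-scale
  scan for recovery.

## Known limitations

* With independent-window noise the block-level test is substantially
  more powerful than on spatially correlated real tracks; simulated
  block p-values are therefore far smaller than real-data ones at the
  same effect size. Comparisons against printed block-level p-values
  require the original tracks and are out of scope.
* In the recovery condition (effect confined to 9 windows, 0.048 per
  allele, SD 0.14, n = 60), the global-minimum placement overlaps the
  true interval in ≈97% of replicates, but the best window *size* lands
  in 9 ± 3 only ≈73–76% of the time: for $w > 9$ the covering
  placement's t-statistic decays only like $\sqrt{9/w}$, so chance
  fluctuations across ~56,000 placements regularly push the argmin to
  moderately larger sizes. Treat `best_w` as scale-indicative, not a
  point estimate; the per-size minima from `tidy()` show the full
  picture.
* The Storey estimator at fixed λ returns $\pi_0 = 0$ (hence q = 0) when
  a *single* small p-value is supplied; q-values are meaningful for
  batches, not singletons.
* `mine_cpg_snp_stats()` fractions depend on the denominator convention
  documented above; other published conventions (reference-CpG overlap)
  will differ.
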