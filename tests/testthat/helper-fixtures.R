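# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, double loops, normal equations) and never call the package
# functions they are used to check.

# --- fixtures -------------------------------------------------------------

# Grid emulating the hg18 FTO LD-block tiling: 459 genomic windows from
# chr16:52,357,000, masked down to 334 usable windows so that unmasked
# index 110 is genomic window 148 (start 52,371,700), unmasked 161-169 are
# genomic 216-224 (52,378,500-52,379,399), and the masked windows never
# touch the narrow peak.
fto_block_grid <- function() {
  mask <- rep(FALSE, 459)
  mask[head(seq(1, 147, by = 3), 38)] <- TRUE   # 38 masked before window 148
  mask[seq(150, 214, by = 4)] <- TRUE           # 17 masked inside the broad peak
  mask[head(seq(225, 459, by = 3), 70)] <- TRUE # 70 masked downstream
  meth_grid("chr16", 52357000, 459, 100, mask = mask)
}

fto_block_region <- function() {
  region("chr16", 52357008, 52402988, label = "FTO_block")
}

# Table of the three CpG-creating/abrogating SNPs in the 900 bp narrow
# peak, with primate-unanimous ancestral bases and the risk/reference
# alleles (reference = major allele; risk haplotype carries the minor).
narrow_peak_snps <- function() {
  tibble::tibble(
    snp_id = c("rs7206629", "rs7202116", "rs7202296"),
    chrom = "chr16",
    pos = c(52378914, 52379116, 52379191),
    left_flank = c("TTGGT", "TAAAC", "AAGCC"),
    allele_a = c("T", "A", "A"),
    allele_b = c("C", "G", "G"),
    right_flank = c("GAAGT", "TCTTT", "ATAAA"),
    ancestral = c("C", "A", "A"),
    ref_allele = c("T", "A", "A"),
    risk_allele = c("C", "G", "G")
  )
}

# --- oracles --------------------------------------------------------------

# Kruskal-Wallis H computed from first principles (midranks + tie term)
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    h <- h + sum(r[sel])^2 / sum(sel)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  t <- table(values)
  h / (1 - sum(t^3 - t) / (n^3 - n))
}

# exact enumeration p for the KW statistic: all distinct assignments of
# the group-label multiset to the observations (feasible for n <= 8)
oracle_kw_exact_p <- function(values, groups) {
  n <- length(values)
  stopifnot(n <= 8)
  h_obs <- oracle_kw_h(values, groups)
  perms <- multiset_permutations(groups)
  hs <- apply(perms, 1, function(g) oracle_kw_h(values, g))
  mean(hs >= h_obs - 1e-12)
}

# all distinct permutations of a label multiset, one per row
multiset_permutations <- function(labels) {
  rec <- function(lab) {
    if (length(lab) == 1L) return(matrix(lab, 1, 1))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      sub <- rec(rest)
      out[[length(out) + 1L]] <- cbind(u, sub)
    }
    do.call(rbind, out)
  }
  m <- rec(labels)
  dimnames(m) <- NULL
  m
}

# OLS by explicit normal equations, with coefficient t-test p-values
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * s2)
  t <- beta / se
  list(beta = as.vector(beta), se = as.vector(se),
       p = as.vector(2 * pt(-abs(t), df)))
}

# global-test Q by explicit double loop over proxies and samples
oracle_global_q <- function(M, y) {
  z <- y - mean(y)
  total <- 0
  for (p in seq_len(nrow(M))) {
    x <- M[p, ] - mean(M[p, ])
    acc <- 0
    for (s in seq_along(z)) acc <- acc + x[s] * z[s]
    total <- total + acc^2
  }
  total / nrow(M)
}

# brute-force single-linkage clustering from the full pairwise distance
# matrix (flood fill over the <= max_dist adjacency graph)
oracle_single_linkage <- function(pos, max_dist) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= max_dist
  cluster <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      cluster[frontier] <- k
      frontier <- which(is.na(cluster) &
                          apply(adj[, frontier, drop = FALSE], 1, any))
    }
  }
  cluster
}

# Storey q-values straight from the definition (double loop)
oracle_qvalues <- function(p) {
  m <- length(p)
  pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  r <- rank(p, ties.method = "max")
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- p >= p[i]
    q[i] <- min(pi0 * m * p[j] / r[j])
  }
  pmin(q, 1)
}
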