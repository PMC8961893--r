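# Independent oracles used across the suite. Each recomputes a quantity
# from its definition by a route different from the package's.

# Conditional HWE exact test by direct evaluation of
# P(het | n, allele counts) with log-factorials over every admissible
# heterozygote count.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Benjamini-Hochberg by literal step-up definition:
# q_(i) = min_{j >= i} min(1, m p_(j) / j), reported in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# IBS FST by enumeration of ordered allele pairs (with replacement):
# fraction of identical pairs within pooled alleles (GT) and within
# groups (GS; group picked either uniformly or proportionally to its
# allele count, matching the two GS weightings).
fst_pair_oracle <- function(counts, weighting = "size") {
  alleles <- apply(counts, 1, function(r) rep(c(0L, 1L), r),
                   simplify = FALSE)
  ibs_frac <- function(v) {
    pairs <- expand.grid(i = seq_along(v), j = seq_along(v))
    mean(v[pairs$i] == v[pairs$j])
  }
  GT <- ibs_frac(unlist(alleles))
  fr <- vapply(alleles, ibs_frac, 0)
  GS <- if (weighting == "size")
    stats::weighted.mean(fr, rowSums(counts)) else mean(fr)
  if (GT >= 1) return(NA_real_)
  (GS - GT) / (1 - GT)
}

# small simulated panel, memoised per test file run
small_panel <- function(...) simulate_panel(sim_config(...))

# dosage panel wrapper for hand-built matrices
toy_panel <- function(calls, scaffold = "s1",
                      pos = seq_len(ncol(calls)) * 1000L,
                      site = rep("A", nrow(calls))) {
  calls <- as.matrix(calls)
  genotype_panel(
    calls,
    variants = data.frame(scaffold = rep_len(scaffold, ncol(calls)),
                          pos = pos, ref = "A", alt = "T",
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(nrow(calls))),
                         site = site, stringsAsFactors = FALSE))
}
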