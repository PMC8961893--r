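#' Single-SNP FST from per-group allele counts (identity-by-state formula)
#'
#' Computes `FST = (GS - GT) / (1 - GT)`, where `GT` is the probability
#' that two alleles drawn from the pooled population are identical by
#' state (`pbar^2 + qbar^2` from pooled frequencies) and `GS` the same
#' probability within groups. The formula itself does not prescribe how
#' groups are combined into `GS`; the default weights each group by its
#' observed allele count, which keeps `GS` and the pooled `GT` on the
#' same footing. With `weighting = "unweighted"` every group counts
#' equally, but beware: under strongly unequal group sizes the
#' unweighted ratio nearly cancels genuine divergence (the pooled
#' frequency stays allele-count weighted), so it is unsuitable as a
#' differentiation estimate for unbalanced designs.
#'
#' @param group_allele_counts matrix with one row per group and columns
#'   `(ref_count, alt_count)`; every group needs at least one observed
#'   allele.
#' @param weighting `"size"` (groups weighted by allele counts, default)
#'   or `"unweighted"` (plain mean of per-group IBS probabilities).
#' @return FST, or `NA` when the pooled site is monomorphic (GT = 1).
#' @export
snp_fst <- function(group_allele_counts,
                    weighting = c("size", "unweighted")) {
  weighting <- match.arg(weighting)
  x <- as.matrix(group_allele_counts)
  if (nrow(x) < 2) stop("need at least two groups")
  tot <- rowSums(x)
  if (any(tot < 1)) stop("group ", which(tot < 1)[1], " has no alleles")
  p <- x[, 2] / tot
  pbar <- sum(x[, 2]) / sum(tot)
  GT <- pbar^2 + (1 - pbar)^2
  ibs <- p^2 + (1 - p)^2
  GS <- if (weighting == "unweighted") mean(ibs)
        else sum(ibs * tot) / sum(tot)
  if (GT >= 1) return(NA_real_)
  (GS - GT) / (1 - GT)
}

# per-SNP FST across all SNPs of a dosage matrix, IBS formula
fst_ibs_per_snp <- function(calls, groups, weighting = "size") {
  labs <- unique(groups)
  alt <- vapply(labs, function(g)
    colSums(calls[groups == g, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(calls)))
  nn <- vapply(labs, function(g)
    colSums(!is.na(calls[groups == g, , drop = FALSE])),
    numeric(ncol(calls)))
  p <- alt / (2 * nn)                       # snp x group
  p[nn == 0] <- NA
  ibs <- p^2 + (1 - p)^2
  GS <- if (weighting == "size")
    rowSums(ibs * nn, na.rm = TRUE) / rowSums(nn * !is.na(ibs))
  else rowMeans(ibs)
  pbar <- rowSums(alt) / (2 * rowSums(nn))
  GT <- pbar^2 + (1 - pbar)^2
  out <- (GS - GT) / (1 - GT)
  out[GT >= 1] <- NA
  out
}

# Weir & Cockerham (1984) per-locus variance components (a, b, c)
fst_wc_components <- function(calls, groups) {
  labs <- unique(groups)
  r <- length(labs)
  m <- ncol(calls)
  nmat <- vapply(labs, function(g)
    colSums(!is.na(calls[groups == g, , drop = FALSE])), numeric(m))
  altm <- vapply(labs, function(g)
    colSums(calls[groups == g, , drop = FALSE], na.rm = TRUE), numeric(m))
  hetm <- vapply(labs, function(g)
    colSums(calls[groups == g, , drop = FALSE] == 1L, na.rm = TRUE),
    numeric(m))
  pm <- altm / (2 * nmat)
  nbar <- rowMeans(nmat)
  nsum <- rowSums(nmat)
  nc <- (nsum - rowSums(nmat^2) / nsum) / (r - 1)
  pbar <- rowSums(nmat * pm) / nsum
  s2 <- rowSums(nmat * (pm - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(hetm) / nsum
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- apply(nmat, 1, function(x) any(x == 0)) | nbar <= 1 | nc <= 0
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  list(a = a, b = b, c = cc)
}

#' Genome-wide mean FST between labelled groups
#'
#' Per-SNP FST values are combined either as their unweighted mean
#' (negative values retained, not clamped) or as a ratio of sums.
#' The default estimator is the identity-by-state formula of
#' [snp_fst()]; `estimator = "wc"` switches to the Weir--Cockerham
#' (1984) variance-components estimator, which is the appropriate
#' choice when the goal is recovering a nominal divergence parameter
#' (the IBS formula is downward/sampling biased at small group counts).
#'
#' @param panel a `genotype_panel` (or dosage matrix).
#' @param groups per-sample group labels (default the panel's `site`).
#' @param estimator `"ibs"` (printed formula) or `"wc"`.
#' @param aggregate `"mean"` (unweighted over SNPs) or `"ratio"`
#'   (ratio of sums; for WC, `sum(a) / sum(a+b+c)`).
#' @param weighting group weighting for the IBS `GS` term, as in
#'   [snp_fst()].
#' @return list with `fst` and `n_snps` (SNPs with a defined value).
#' @export
mean_fst <- function(panel, groups = NULL,
                     estimator = c("ibs", "wc"),
                     aggregate = c("mean", "ratio"),
                     weighting = c("size", "unweighted")) {
  estimator <- match.arg(estimator)
  aggregate <- match.arg(aggregate)
  weighting <- match.arg(weighting)
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else
    as.matrix(panel)
  if (is.null(groups)) groups <- panel$samples$site
  if (length(unique(groups)) < 2) stop("need at least two groups")
  if (estimator == "ibs") {
    fst <- fst_ibs_per_snp(calls, groups, weighting)
    ok <- !is.na(fst)
    if (!any(ok)) stop("no SNP has a defined FST")
    val <- if (aggregate == "mean") mean(fst[ok]) else {
      labs <- unique(groups)
      # ratio of sums on the same formula's numerator/denominator
      alt <- vapply(labs, function(g)
        colSums(calls[groups == g, , drop = FALSE], na.rm = TRUE),
        numeric(ncol(calls)))
      nn <- vapply(labs, function(g)
        colSums(!is.na(calls[groups == g, , drop = FALSE])),
        numeric(ncol(calls)))
      p <- alt / (2 * nn)
      ibs <- p^2 + (1 - p)^2
      GS <- if (weighting == "size")
        rowSums(ibs * nn, na.rm = TRUE) / rowSums(nn * !is.na(ibs))
      else rowMeans(ibs)
      pbar <- rowSums(alt) / (2 * rowSums(nn))
      GT <- pbar^2 + (1 - pbar)^2
      sum((GS - GT)[ok]) / sum((1 - GT)[ok])
    }
  } else {
    comp <- fst_wc_components(calls, groups)
    ok <- !is.na(comp$a)
    if (!any(ok)) stop("no SNP has a defined FST")
    val <- if (aggregate == "ratio")
      sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
    else {
      f <- comp$a / (comp$a + comp$b + comp$c)
      mean(f[ok & is.finite(f)])
    }
  }
  list(fst = val, n_snps = sum(ok))
}

#' Permutation test for genome-wide and per-SNP FST
#'
#' Group labels are shuffled across samples `n_perm` times; the global
#' p-value is `(1 + #permuted mean >= observed mean) / (1 + n_perm)`
#' (add-one convention, so 10,000 permutations give a floor of
#' ~1.0e-4), and per-SNP p-values are computed the same way from each
#' SNP's permuted values. Benjamini--Hochberg q-values are attached and
#' SNPs with `q <= fdr_alpha` flagged as stratification-informative.
#' Uses the identity-by-state FST of [snp_fst()], vectorized across
#' permutations; the estimator's finite-sample bias is immaterial here
#' because it is shared by the permutation null.
#'
#' @param panel a `genotype_panel` (or dosage matrix).
#' @param groups per-sample labels (default the panel `site` column).
#' @param n_perm number of permutations (>= 1; the study used 10,000).
#' @param seed integer seed (label shuffles are the only randomness).
#' @param fdr_alpha informative-SNP threshold on q-values.
#' @param chunk permutations processed per matrix-product block.
#' @param weighting group weighting for the IBS `GS` term, as in
#'   [snp_fst()].
#' @return An `fst_result` list: `per_snp_fst`, `mean_fst`,
#'   `perm_p_global`, `perm_p_per_snp`, `q_per_snp`, `informative`
#'   (SNP indices), `n_perm`.
#' @export
fst_permutation <- function(panel, groups = NULL, n_perm = 10000,
                            seed = 1, fdr_alpha = 0.05, chunk = 500,
                            weighting = c("size", "unweighted")) {
  weighting <- match.arg(weighting)
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else
    as.matrix(panel)
  if (is.null(groups)) groups <- panel$samples$site
  groups <- as.character(groups)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(calls); m <- ncol(calls)
  labs <- unique(groups)
  G <- length(labs)
  if (G < 2) stop("need at least two groups")

  X0 <- calls; X0[is.na(X0)] <- 0L
  storage.mode(X0) <- "double"
  M <- (!is.na(calls)) * 1

  fst_for_labels <- function(lab_mat) {
    # lab_mat: chunk x n matrix of integer group codes (1..G)
    B <- nrow(lab_mat)
    GS <- matrix(0, B, m)
    W <- matrix(0, B, m)
    for (g in seq_len(G)) {
      Ig <- (lab_mat == g) * 1
      altg <- Ig %*% X0
      nng <- Ig %*% M
      pg <- altg / (2 * nng)
      pg[nng == 0] <- NA
      ibs_g <- pg^2 + (1 - pg)^2
      if (weighting == "size") {
        ok <- !is.na(ibs_g)
        ibs_g[!ok] <- 0
        GS <- GS + ibs_g * nng
        W <- W + nng * ok
      } else {
        GS <- GS + ibs_g
      }
    }
    GS <- if (weighting == "size") GS / W else GS / G
    alt_tot <- colSums(X0)
    nn_tot <- colSums(M)
    pbar <- alt_tot / (2 * nn_tot)
    GT <- pbar^2 + (1 - pbar)^2          # label-invariant
    f <- sweep(GS, 2, GT, `-`)
    f <- sweep(f, 2, 1 - GT, `/`)
    f[, GT >= 1] <- NA
    f
  }

  codes <- match(groups, labs)
  obs <- fst_for_labels(matrix(codes, 1))[1, ]
  obs_mean <- mean(obs, na.rm = TRUE)

  set.seed(seed)
  ge_global <- 0L
  ge_snp <- integer(m)
  done <- 0L
  while (done < n_perm) {
    B <- min(chunk, n_perm - done)
    lab_mat <- t(vapply(seq_len(B), function(i) sample(codes), codes))
    f <- fst_for_labels(lab_mat)
    pm <- rowMeans(f, na.rm = TRUE)
    ge_global <- ge_global + sum(pm >= obs_mean)
    cmp <- sweep(f, 2, obs, `>=`)
    ge_snp <- ge_snp + colSums(cmp, na.rm = TRUE)
    done <- done + B
  }
  p_global <- (1 + ge_global) / (1 + n_perm)
  p_snp <- (1 + ge_snp) / (1 + n_perm)
  p_snp[is.na(obs)] <- NA
  q <- rep(NA_real_, m)
  q[!is.na(p_snp)] <- stats::p.adjust(p_snp[!is.na(p_snp)], "BH")
  structure(list(per_snp_fst = obs, mean_fst = obs_mean,
                 perm_p_global = p_global, perm_p_per_snp = p_snp,
                 q_per_snp = q,
                 informative = which(!is.na(q) & q <= fdr_alpha),
                 n_perm = n_perm),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("FST permutation test:", length(x$per_snp_fst), "SNPs,",
      x$n_perm, "permutations\n")
  cat("  genome-wide mean FST:", signif(x$mean_fst, 4),
      " p =", signif(x$perm_p_global, 4), "\n")
  cat("  informative SNPs (BH q <= 0.05):", length(x$informative), "\n")
  invisible(x)
}

#' PCA of a genotype panel
#'
#' Missing dosages are mean-imputed per SNP; columns are centered and
#' variance-standardized before eigendecomposition of the sample
#' covariance. SNPs with zero variance after imputation are dropped.
#'
#' @param panel a `genotype_panel` or dosage matrix.
#' @param snp_subset optional variant indices (e.g. the
#'   stratification-informative SNPs from [fst_permutation()]).
#' @param n_pc number of components to return.
#' @return list with `coords` (samples x PCs), `eigenvalues`
#'   (all, non-increasing) and `n_dropped`.
#' @export
pca_panel <- function(panel, snp_subset = NULL, n_pc = 10) {
  X <- if (inherits(panel, "genotype_panel")) panel$calls else
    as.matrix(panel)
  if (!is.null(snp_subset)) {
    if (length(snp_subset) == 0) stop("empty SNP subset")
    X <- X[, snp_subset, drop = FALSE]
  }
  if (nrow(X) < 2) stop("need at least two samples")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  sds <- apply(X, 2, stats::sd)
  drop <- sds == 0 | is.na(sds)
  X <- X[, !drop, drop = FALSE]
  if (ncol(X) == 0) stop("no variable SNPs left")
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_pc, ncol(pr$x))
  list(coords = pr$x[, seq_len(k), drop = FALSE],
       eigenvalues = pr$sdev^2,
       n_dropped = sum(drop))
}

#' Optimal k for k-means by the TWSS plateau rule
#'
#' k-means is run for `k = 1..k_max` with `n_restarts` random starts
#' each (the best total within-cluster sum of squares, TWSS, is kept;
#' monotonicity of TWSS in k is enforced by also warm-starting each k
#' from the previous solution with its worst-fit point split off). The
#' optimal k is the smallest k whose relative TWSS improvement from k
#' to k+1 falls below the plateau threshold `delta` while the
#' improvement from k-1 to k (when k > 1) is at least `delta`.
#'
#' @param coords numeric matrix of sample coordinates (typically the
#'   top principal components).
#' @param k_max largest k considered.
#' @param n_restarts random restarts per k.
#' @param seed integer seed.
#' @param delta plateau threshold on relative TWSS improvement
#'   (default 0.10).
#' @return list with `twss_by_k`, `rel_improvement`, `optimal_k` and
#'   `assignments` (for the optimal k).
#' @export
optimal_k_twss <- function(coords, k_max = 10, n_restarts = 10, seed = 1,
                           delta = 0.10) {
  coords <- as.matrix(coords)
  if (k_max < 2) stop("k_max must be >= 2")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (nrow(coords) < k_max) stop("fewer samples than k_max")
  set.seed(seed)
  twss <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    km <- suppressWarnings(
      stats::kmeans(coords, centers = k, nstart = n_restarts,
                    iter.max = 50))
    if (k > 1) {
      # warm start: previous centers plus the point farthest from its
      # centroid; k-means iterations cannot worsen this objective
      prev <- fits[[k - 1]]
      resid <- rowSums((coords - prev$centers[prev$cluster, ,
                                              drop = FALSE])^2)
      cand <- rbind(prev$centers, coords[which.max(resid), , drop = FALSE])
      cand <- cand + stats::rnorm(length(cand)) * 1e-9  # avoid duplicates
      km2 <- suppressWarnings(
        stats::kmeans(coords, centers = cand, iter.max = 50))
      if (km2$tot.withinss < km$tot.withinss) km <- km2
    }
    twss[k] <- km$tot.withinss
    fits[[k]] <- km
  }
  rel <- c(NA, ifelse(twss[-k_max] > 0,
                      (twss[-k_max] - twss[-1]) / twss[-k_max], 0))
  opt <- k_max
  for (k in seq_len(k_max - 1)) {
    gain_in <- if (k == 1) TRUE else rel[k] >= delta
    if (gain_in && rel[k + 1] < delta) { opt <- k; break }
  }
  list(twss_by_k = twss, rel_improvement = rel, optimal_k = opt,
       assignments = fits[[opt]]$cluster)
}

#' Pearson chi-square test of independence for a contingency table
#'
#' No continuity correction; `df = (rows - 1)(cols - 1)`. Used for the
#' cluster-by-collection-site association.
#'
#' @param table matrix of non-negative counts, at least 2x2, with no
#'   zero row/column margin.
#' @return list with `chi2`, `df`, `p`.
#' @export
contingency_chi2 <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2 || ncol(x) < 2) stop("table must be at least 2x2")
  if (any(x < 0)) stop("negative counts")
  if (sum(x) <= 0) stop("empty table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("zero row/column margin")
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
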