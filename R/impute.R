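#' Maximum-likelihood alternative-allele frequency from genotype likelihoods
#'
#' EM estimate of the site allele frequency under Hardy--Weinberg, with
#' genotype likelihoods `10^(-PL/10)` as the data model: at each step,
#' per-sample genotype posteriors are formed against the current
#' HWE prior and the frequency is updated to the posterior mean dosage
#' over two. Convergence when the frequency moves less than `tol`
#' (default 1e-8) or after `max_iter` iterations.
#'
#' When every PL triple is flat (no read evidence anywhere) the
#' estimate is undefined; 0.5 is returned with a warning and the
#' attribute `flat = TRUE`.
#'
#' @param pls numeric matrix `n_samples x 3` of phred-scaled likelihoods
#'   in VCF genotype order (hom-ref, het, hom-alt).
#' @param tol,max_iter convergence controls.
#' @return Frequency in \[0, 1\].
#' @export
em_site_frequency <- function(pls, tol = 1e-8, max_iter = 100) {
  pls <- as.matrix(pls)
  stopifnot(ncol(pls) == 3, nrow(pls) >= 1)
  lik <- 10^(-pls / 10)
  informative <- apply(lik, 1, function(r) diff(range(r)) > 0)
  if (!any(informative)) {
    warning("all PL triples are flat; frequency undefined, returning 0.5")
    return(structure(0.5, flat = TRUE))
  }
  # initialize at the frequency implied by likelihood-maximizing calls
  calls <- max.col(lik, ties.method = "first") - 1L
  p <- mean(calls[informative]) / 2
  if (p <= 0 || p >= 1) p <- 0.5
  for (it in seq_len(max_iter)) {
    prior <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    post <- sweep(lik, 2, prior, `*`)
    post <- post / rowSums(post)
    p_new <- mean(post[, 2] / 2 + post[, 3])
    if (abs(p_new - p) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  p
}

#' Genotype posteriors from PL and a site allele frequency
#'
#' Posterior proportional to `10^(-PL/10)` times the Hardy--Weinberg
#' prior `((1-p)^2, 2p(1-p), p^2)` in VCF genotype order, normalized to
#' sum to one. A degenerate frequency (0 or 1) concentrates the prior,
#' and hence the posterior, on the corresponding homozygote regardless
#' of PL.
#'
#' @param pls numeric vector of 3 phred values, or an `n x 3` matrix.
#' @param freq alternative-allele frequency in \[0, 1\].
#' @return Probability triple (or `n x 3` matrix of them).
#' @export
genotype_posteriors <- function(pls, freq) {
  stopifnot(freq >= 0, freq <= 1)
  vec <- is.null(dim(pls))
  pls <- rbind(pls)
  if (ncol(pls) != 3) stop("PL must have 3 entries per genotype")
  prior <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  post <- sweep(10^(-pls / 10), 2, prior, `*`)
  s <- rowSums(post)
  zero <- s == 0
  post[!zero, ] <- post[!zero, , drop = FALSE] / s[!zero]
  if (any(zero))   # prior support and likelihood support disjoint
    post[zero, ] <- matrix(prior / sum(prior), sum(zero), 3, byrow = TRUE)
  if (vec) drop(post) else post
}

#' Compute genotype posteriors for every cell of a panel
#'
#' Runs [em_site_frequency()] per site on the panel's PL field and
#' stores the resulting GP array. Panels that already carry GP (for
#' example, read from an externally imputed VCF) are returned unchanged,
#' so an external imputer's posteriors flow through the same gate.
#'
#' @param panel a `genotype_panel` with a `pl` array.
#' @return The panel with `gp` filled and per-site EM frequencies in
#'   attribute `alt_freq_mle`.
#' @export
compute_genotype_posteriors <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(panel$gp)) return(panel)
  if (is.null(panel$pl)) stop("panel carries neither GP nor PL")
  n <- nrow(panel$calls); m <- ncol(panel$calls)
  gp <- array(NA_real_, c(n, m, 3))
  freqs <- numeric(m)
  for (j in seq_len(m)) {
    plj <- cbind(panel$pl[, j, 1], panel$pl[, j, 2], panel$pl[, j, 3])
    f <- suppressWarnings(em_site_frequency(plj))
    freqs[j] <- f
    gp[, j, ] <- genotype_posteriors(plj, f)
  }
  panel$gp <- gp
  attr(panel, "alt_freq_mle") <- freqs
  panel
}

#' Impute masked genotypes subject to a posterior-probability gate
#'
#' Each genotype previously flagged by [mask_low_confidence()] is
#' replaced by its posterior-maximizing dosage when the maximum
#' genotype posterior reaches `gp_min`, and set missing otherwise
#' (failed-gate genotypes therefore count as missing data in later
#' site filters). Unmasked genotypes keep their original calls.
#'
#' @param panel a masked `genotype_panel`; GP is computed from PL via
#'   [compute_genotype_posteriors()] if absent.
#' @param gp_min acceptance threshold on the maximum posterior, in
#'   (0, 1\] (default 0.95).
#' @return list with `panel` (imputed calls, GP attached, mask cleared),
#'   `n_imputed` and `n_set_missing`.
#' @export
apply_imputation <- function(panel, gp_min = 0.95) {
  stopifnot(inherits(panel, "genotype_panel"),
            gp_min > 0, gp_min <= 1)
  if (is.null(panel$mask))
    stop("panel has no imputation mask; run mask_low_confidence() first")
  panel <- compute_genotype_posteriors(panel)
  n <- nrow(panel$calls); m <- ncol(panel$calls)
  gp_flat <- matrix(c(panel$gp), n * m, 3)
  best <- max.col(gp_flat, ties.method = "first")
  best_p <- gp_flat[cbind(seq_len(n * m), best)]
  masked <- as.vector(panel$mask)
  accept <- masked & best_p >= gp_min
  reject <- masked & !accept
  calls <- as.vector(panel$calls)
  calls[accept] <- best[accept] - 1L
  calls[reject] <- NA_integer_
  panel$calls <- matrix(as.integer(calls), n, m,
                        dimnames = dimnames(panel$calls))
  panel$mask <- NULL
  list(panel = panel, n_imputed = sum(accept),
       n_set_missing = sum(reject))
}
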