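#' Species-identification filter on best BLAST hits
#'
#' Applies the discard rules used for COI-based species confirmation:
#' a specimen's best hit is kept only when the e-value is at most
#' 1e-100, at least 200 positions are identical, percent identity is at
#' least 90 and the subject taxon matches the target species.
#'
#' @param hits data.frame with columns `query_id`, `subject_taxon`,
#'   `evalue`, `identities`, `identity_pct` (one best hit per specimen).
#' @param target_taxon taxon string a kept hit must match exactly.
#' @param evalue_max,identities_min,identity_pct_min thresholds.
#' @return A list with `kept` and `discarded` data.frames; `discarded`
#'   gains a `reason` column. Records with a negative e-value or a
#'   percent identity outside \[0, 100\] are discarded with reason
#'   `"invalid_record"`.
#' @export
filter_blast_hits <- function(hits, target_taxon,
                              evalue_max = 1e-100,
                              identities_min = 200,
                              identity_pct_min = 90) {
  need <- c("query_id", "subject_taxon", "evalue", "identities",
            "identity_pct")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  invalid <- hits$evalue < 0 | hits$identity_pct < 0 |
    hits$identity_pct > 100 | hits$identities < 0
  invalid[is.na(invalid)] <- TRUE
  reason <- rep(NA_character_, nrow(hits))
  reason[invalid] <- "invalid_record"
  ok <- !invalid
  fail_e <- ok & hits$evalue > evalue_max
  fail_i <- ok & hits$identities < identities_min
  fail_p <- ok & hits$identity_pct < identity_pct_min
  fail_t <- ok & hits$subject_taxon != target_taxon
  reason[fail_t] <- "wrong_taxon"
  reason[fail_p] <- "identity_pct"
  reason[fail_i] <- "identities"
  reason[fail_e] <- "evalue"
  keep <- ok & !fail_e & !fail_i & !fail_p & !fail_t
  discarded <- hits[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  list(kept = hits[keep, , drop = FALSE], discarded = discarded)
}

#' Read BLAST tabular output (outfmt-6 style)
#'
#' @param path tabular BLAST file without header.
#' @param col_names column names in file order; defaults to the standard
#'   12-column outfmt 6 layout with the subject field used as taxon.
#'   When no `identities` column is present it is derived as
#'   `align_length - mismatches`.
#' @return data.frame suitable for [filter_blast_hits()].
#' @export
read_blast_tab <- function(path,
                           col_names = c("query_id", "subject_taxon",
                                         "identity_pct", "align_length",
                                         "mismatches", "gap_opens",
                                         "qstart", "qend", "sstart",
                                         "send", "evalue", "bitscore")) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[seq_along(col_names)] <- col_names
  if (!"identities" %in% names(d) &&
      all(c("align_length", "mismatches") %in% names(d)))
    d$identities <- d$align_length - d$mismatches
  d
}

#' Mask low-confidence genotypes for imputation
#'
#' A genotype is queued for imputation when its read depth or phred
#' genotype quality falls below threshold (strictly: `DP < dp_min` or
#' `GQ < gq_min`); all other genotypes are untouched.
#'
#' @param panel a `genotype_panel` carrying `dp` and `gq`.
#' @param dp_min minimum read depth (default 5).
#' @param gq_min minimum genotype quality (default 20).
#' @return A list with `panel` (mask attached) and `n_masked`.
#' @export
mask_low_confidence <- function(panel, dp_min = 5, gq_min = 20) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$dp) || is.null(panel$gq))
    stop("panel lacks DP/GQ fields; cannot mask")
  bad_dp <- is.na(panel$dp)
  bad_gq <- is.na(panel$gq)
  if (any(bad_dp) || any(bad_gq)) {
    w <- which(bad_dp | bad_gq, arr.ind = TRUE)[1, ]
    stop("missing DP/GQ for sample ", rownames(panel$calls)[w[1]],
         " at ", colnames(panel$calls)[w[2]])
  }
  mask <- panel$dp < dp_min | panel$gq < gq_min
  panel$mask <- mask
  list(panel = panel, n_masked = sum(mask))
}

#' Site-level filter configuration
#'
#' Thresholds default to the working values of the low-coverage
#' pipeline: MAF 0.1, mode-specific missing-data ceilings (0.5 before
#' imputation, 0.3 after, 0.8 for never-imputed panels), within-stratum
#' Hardy--Weinberg alpha 0.001, and at least 15 non-missing genotypes
#' per stratum for raw panels.
#'
#' Boundary semantics are strict, exactly as the rules are usually
#' quoted: `pre_imputation` removes sites with MAF < 0.1 or MD > 0.5
#' (a site at MAF exactly 0.1 survives), while `post_imputation` and
#' `raw` keep sites with MAF > 0.1 and MD below the ceiling (a site at
#' MAF exactly 0.1 is removed).
#'
#' @param mode one of `"pre_imputation"`, `"post_imputation"`, `"raw"`.
#' @param maf_min,md_max,hwe_alpha,min_nonmissing_per_stratum thresholds;
#'   `md_max` defaults by mode as above.
#' @return A `filter_config` list.
#' @export
filter_config <- function(mode = c("pre_imputation", "post_imputation",
                                   "raw"),
                          maf_min = 0.1,
                          md_max = NULL,
                          hwe_alpha = 0.001,
                          min_nonmissing_per_stratum = 15) {
  mode <- match.arg(mode)
  if (is.null(md_max))
    md_max <- switch(mode, pre_imputation = 0.5, post_imputation = 0.3,
                     raw = 0.8)
  stopifnot(maf_min >= 0, maf_min <= 0.5, md_max >= 0, md_max <= 1,
            hwe_alpha > 0, hwe_alpha < 1, min_nonmissing_per_stratum >= 0)
  structure(list(mode = mode, maf_min = maf_min, md_max = md_max,
                 hwe_alpha = hwe_alpha,
                 min_nonmissing_per_stratum = min_nonmissing_per_stratum),
            class = "filter_config")
}

site_maf <- function(calls) {
  # minor-allele frequency per site over non-missing calls; NA if no calls
  nn <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- alt / (2 * nn)
  pmin(p, 1 - p)
}

site_md <- function(calls) colMeans(is.na(calls))

#' Site-level panel filters (MAF, missingness, stratum support, HWE)
#'
#' Applies the mode-specific keep rules described in [filter_config()].
#' Each removed site is attributed to the first failed rule in the
#' fixed order MAF, MD, per-stratum non-missing support, HWE, so that
#' per-rule counts sum to the total number of removals. Monomorphic
#' sites have MAF 0 and fall to the MAF rule; all-missing sites have
#' undefined MAF and are likewise attributed to the MAF rule.
#'
#' The Hardy--Weinberg exact test runs within every stratum
#' (collection site), screening for a Wahlund effect; a site is removed
#' when any stratum's p-value falls below `hwe_alpha`.
#'
#' @param panel a `genotype_panel`; `panel$samples$site` supplies the
#'   strata when the mode needs them.
#' @param config a [filter_config()].
#' @return list with `panel` (filtered), `removed` (named per-rule
#'   counts), and `kept` (number of surviving sites).
#' @export
site_filters <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "filter_config"))
  calls <- panel$calls
  m <- ncol(calls)
  maf <- site_maf(calls)
  md <- site_md(calls)
  fail_maf <- if (config$mode == "pre_imputation")
    is.na(maf) | maf < config$maf_min
  else
    is.na(maf) | maf <= config$maf_min
  fail_md <- if (config$mode == "pre_imputation")
    md > config$md_max
  else
    md >= config$md_max

  needs_strata <- config$mode %in% c("post_imputation", "raw")
  fail_support <- rep(FALSE, m)
  fail_hwe <- rep(FALSE, m)
  if (needs_strata) {
    if (is.null(panel$samples$site))
      stop("mode '", config$mode, "' needs a site column in sample metadata")
    strata <- split(seq_len(nrow(calls)), panel$samples$site)
    live <- which(!(fail_maf | fail_md))   # HWE only assessed on survivors
    cache <- new.env(parent = emptyenv())
    for (idx in strata) {
      sub <- calls[idx, live, drop = FALSE]
      nn <- colSums(!is.na(sub))
      if (config$mode == "raw")
        fail_support[live][nn < config$min_nonmissing_per_stratum] <- TRUE
      n_aa <- colSums(sub == 2L, na.rm = TRUE)
      n_het <- colSums(sub == 1L, na.rm = TRUE)
      n_rr <- nn - n_aa - n_het
      for (k in seq_along(live)) {
        j <- live[k]
        if (fail_support[j] || fail_hwe[j] || nn[k] == 0L) next
        key <- paste(n_rr[k], n_het[k], n_aa[k])
        p <- cache[[key]]
        if (is.null(p)) {
          p <- hwe_exact_test(n_rr[k], n_het[k], n_aa[k])
          cache[[key]] <- p
        }
        if (p < config$hwe_alpha) fail_hwe[j] <- TRUE
      }
    }
    fail_support <- fail_support & !(fail_maf | fail_md)
    fail_hwe <- fail_hwe & !(fail_maf | fail_md | fail_support)
  }
  fail_md <- fail_md & !fail_maf
  keep <- !(fail_maf | fail_md | fail_support | fail_hwe)
  removed <- c(maf = sum(fail_maf), md = sum(fail_md),
               stratum_support = sum(fail_support), hwe = sum(fail_hwe))
  list(panel = panel[, keep], removed = removed, kept = sum(keep))
}

#' Exact test of Hardy--Weinberg equilibrium from genotype counts
#'
#' Conditional exact test on the number of heterozygotes given the
#' allele counts: the p-value is the total probability of all
#' heterozygote configurations no more probable than the observed one
#' (two-sided; mid-p is not used). Probabilities follow the standard
#' recurrence across heterozygote counts of matching parity.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1))
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_r <- (rare - h) / 2          # rare-allele homozygotes at h hets
    hom_c <- (max(nA, na) - h) / 2
    lp[i] <- lp[i - 1] + log(4 * hom_r * hom_c) -
      log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Specimen accounting across collection origins
#'
#' @param captured named vector of specimens captured per origin.
#' @param discarded named vector of specimens discarded per origin
#'   (species-ID failures, low coverage), same order.
#' @return list with `retained` per origin and `total`.
#' @export
sample_accounting <- function(captured, discarded) {
  if (length(captured) != length(discarded))
    stop("captured and discarded must align")
  if (any(discarded > captured))
    stop("cannot discard more specimens than captured")
  retained <- captured - discarded
  list(retained = retained, total = sum(retained))
}
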