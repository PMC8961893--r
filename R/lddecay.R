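#' Pairwise linkage disequilibrium between two dosage vectors
#'
#' r^2 is the squared Pearson correlation of genotype dosages over the
#' samples where both calls are non-missing.
#'
#' @param dosages_a,dosages_b numeric vectors of dosages (NA = missing).
#' @return r^2 in \[0, 1\], or `NA` when fewer than two complete pairs
#'   remain or either vector is constant over the complete subset.
#' @export
pairwise_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Average r^2 in physical-distance bins
#'
#' Every intra-scaffold marker pair at distance `d` with
#' `1 <= d <= n_bins * bin_width` contributes its r^2 to the half-open
#' bin `ceiling(d / bin_width)`; cross-scaffold pairs are excluded.
#' Defaults follow the standard profile of forty 500-bp windows
#' spanning 20 kb.
#'
#' @param panel a `genotype_panel` with variants sorted by scaffold and
#'   position (the simulator and VCF reader produce sorted panels).
#' @param bin_width bin width in bp.
#' @param n_bins number of bins.
#' @return An `ld_profile` data.frame: `bin`, `midpoint`, `mean_r2`,
#'   `se_r2`, `n_pairs`. Empty bins carry `n_pairs = 0` and `NA` means.
#' @export
bin_ld_by_distance <- function(panel, bin_width = 500, n_bins = 40) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  max_d <- bin_width * n_bins
  sums <- numeric(n_bins); sqs <- numeric(n_bins); cnt <- integer(n_bins)
  for (s in unique(v$scaffold)) {
    idx <- which(v$scaffold == s)
    idx <- idx[order(v$pos[idx])]
    if (length(idx) < 2) next
    X <- panel$calls[, idx, drop = FALSE]
    suppressWarnings(C <- stats::cor(X, use = "pairwise.complete.obs"))
    pos <- v$pos[idx]
    d <- abs(outer(pos, pos, `-`))
    ut <- upper.tri(d)
    sel <- ut & d >= 1 & d <= max_d
    r2 <- C[sel]^2
    bins <- ceiling(d[sel] / bin_width)
    keep <- !is.na(r2)
    if (!any(keep)) next
    bins <- bins[keep]; r2 <- r2[keep]
    sums <- sums + vapply(seq_len(n_bins),
                          function(b) sum(r2[bins == b]), 0)
    sqs <- sqs + vapply(seq_len(n_bins),
                        function(b) sum(r2[bins == b]^2), 0)
    cnt <- cnt + vapply(seq_len(n_bins),
                        function(b) sum(bins == b), 0L)
  }
  mean_r2 <- ifelse(cnt > 0, sums / cnt, NA_real_)
  var_r2 <- ifelse(cnt > 1, (sqs - cnt * mean_r2^2) / (cnt - 1), NA_real_)
  se_r2 <- ifelse(cnt > 1, sqrt(pmax(var_r2, 0) / cnt), NA_real_)
  structure(data.frame(bin = seq_len(n_bins),
                       midpoint = (seq_len(n_bins) - 0.5) * bin_width,
                       mean_r2 = mean_r2, se_r2 = se_r2, n_pairs = cnt),
            class = c("ld_profile", "data.frame"))
}

#' Fit the 1/log(distance) LD-decay model
#'
#' Least-squares fit of mean r^2 on the transformed predictor
#' `1 / ln(distance)` (natural logarithm), i.e. the nonlinear decay
#' model `Yhat = beta0 + beta1 / ln(x)`, which is linear after the
#' transform. A pointwise lower 95% confidence curve for the mean
#' response is attached for threshold solving on the conservative band.
#'
#' @param profile an `ld_profile` (or data.frame with `midpoint` and
#'   `mean_r2`); bins with undefined means are dropped. At least three
#'   defined bins are required.
#' @param conf_level confidence level for the band.
#' @return An `ld_decay_fit` list: `beta0`, `beta1`, `r_squared`,
#'   `residual_se`, `lower_band` (per retained bin), `midpoints`, and
#'   the underlying `lm` fit.
#' @export
fit_decay <- function(profile, conf_level = 0.95) {
  d <- as.data.frame(profile)
  d <- d[!is.na(d$mean_r2), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 bins with defined mean r^2")
  z <- 1 / log(d$midpoint)
  if (stats::var(z) == 0) stop("all bin midpoints equal; fit is singular")
  fit <- stats::lm(mean_r2 ~ z, data = data.frame(mean_r2 = d$mean_r2,
                                                  z = z))
  # summary.lm warns on exact fits (noiseless inputs); that is expected here
  sm <- suppressWarnings(summary(fit))
  band <- stats::predict(fit, newdata = data.frame(z = z),
                         interval = "confidence", level = conf_level)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 residual_se = sm$sigma,
                 lower_band = band[, "lwr"],
                 midpoints = d$midpoint,
                 conf_level = conf_level,
                 lm_fit = fit),
            class = "ld_decay_fit")
}

#' Evaluate a fitted LD-decay curve
#'
#' @param fit an `ld_decay_fit`.
#' @param x distances in bp (> 1).
#' @return Predicted mean r^2.
#' @export
predict_decay <- function(fit, x) fit$beta0 + fit$beta1 / log(x)

#' Distance at which the decay curve crosses an r^2 threshold
#'
#' Point-estimate mode inverts the fitted curve in closed form,
#' `x* = exp(beta1 / (threshold - beta0))`. Lower-band mode root-finds
#' the distance where the pointwise lower confidence curve for the mean
#' response crosses the threshold (the conservative choice for a
#' pruning window).
#'
#' @param fit an `ld_decay_fit` with `beta1 > 0` (a decaying curve).
#' @param threshold target mean r^2; must exceed `beta0`, the
#'   asymptote.
#' @param use_lower_band solve on the lower confidence curve instead of
#'   the point estimate.
#' @return Crossing distance in bp.
#' @export
solve_crossing <- function(fit, threshold = 0.1, use_lower_band = FALSE) {
  stopifnot(inherits(fit, "ld_decay_fit"))
  if (threshold <= fit$beta0)
    stop("threshold ", threshold, " is at or below the asymptote beta0 = ",
         signif(fit$beta0, 4), "; the curve never crosses it")
  if (fit$beta1 <= 0)
    stop("beta1 <= 0: fitted curve does not decay")
  if (!use_lower_band)
    return(exp(fit$beta1 / (threshold - fit$beta0)))
  lower_at <- function(x) {
    b <- stats::predict(fit$lm_fit, newdata = data.frame(z = 1 / log(x)),
                        interval = "confidence", level = fit$conf_level)
    b[, "lwr"] - threshold
  }
  lo <- max(min(fit$midpoints), 1.5)
  hi <- max(fit$midpoints) * 100
  if (lower_at(lo) < 0)
    stop("lower band is already below the threshold at the first bin")
  stats::uniroot(lower_at, c(lo, hi), tol = 1e-6)$root
}

#' Greedy window-based LD pruning
#'
#' Left-to-right scan per scaffold in position order: a marker is
#' removed when its r^2 with any already-retained marker within
#' `window` bp upstream exceeds `r2_max`. Deterministic given the input
#' order.
#'
#' @param panel a `genotype_panel`.
#' @param window window size in bp (the study's adopted value, 14 kb).
#' @param r2_max retention threshold on pairwise r^2 (default 0.1).
#' @return list with `keep` (variant indices retained, in panel order)
#'   and `n_removed`.
#' @export
prune_ld <- function(panel, window = 14000, r2_max = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"), window > 0,
            r2_max > 0, r2_max <= 1)
  v <- panel$variants
  keep <- logical(nrow(v))
  for (s in unique(v$scaffold)) {
    idx <- which(v$scaffold == s)
    idx <- idx[order(v$pos[idx])]
    retained <- integer(0)
    for (j in idx) {
      near <- retained[v$pos[retained] >= v$pos[j] - window]
      drop <- FALSE
      for (k in rev(near)) {
        r2 <- pairwise_r2(panel$calls[, j], panel$calls[, k])
        if (!is.na(r2) && r2 > r2_max) { drop <- TRUE; break }
      }
      if (!drop) retained <- c(retained, j)
    }
    keep[retained] <- TRUE
  }
  list(keep = which(keep), n_removed = sum(!keep))
}
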