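test_that("pairwise r2 is the squared dosage correlation over complete pairs", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  a <- c(0, 1, 2, 2, 0); b <- c(0, 1, 1, 2, 0)
  expect_equal(pairwise_r2(a, b), cor(a, b)^2)
  # missing entries restrict to the complete subset
  expect_equal(pairwise_r2(c(0, 1, 2, NA), c(NA, 1, 2, 0)),
               cor(c(1, 2), c(1, 2))^2)
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
})

test_that("distance binning assigns pairs to half-open 500-bp bins", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 3), ncol = 3)
  p <- toy_panel(calls, pos = c(100L, 850L, 21000L))
  prof <- bin_ld_by_distance(p)
  expect_equal(prof$n_pairs[2], 1)       # 750 bp -> bin 2 (501-1000]
  expect_equal(sum(prof$n_pairs), 1)     # 20,900 and 20,150 bp excluded
  # a pair at exactly 20,001 bp is beyond the profile
  p2 <- toy_panel(calls[, 1:2], pos = c(1L, 20002L))
  expect_equal(sum(bin_ld_by_distance(p2)$n_pairs), 0)
  # cross-scaffold pairs never contribute
  p3 <- toy_panel(calls[, 1:2], scaffold = c("s1", "s2"),
                  pos = c(100L, 600L))
  expect_equal(sum(bin_ld_by_distance(p3)$n_pairs), 0)
})

test_that("binned means match an all-pairs recomputation on LD-planted data", {
  sim <- small_panel(n_subpops = 1, samples_per_subpop = 40, n_snps = 150,
                     mean_depth = 30, n_scaffolds = 2,
                     scaffold_length = 60000, ld_rate = 2e-4, seed = 71)
  prof <- bin_ld_by_distance(sim$panel)
  v <- sim$panel$variants
  agg <- matrix(0, 40, 2)                 # sums and counts per bin
  for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
    if (v$scaffold[i] != v$scaffold[j]) next
    d <- abs(v$pos[j] - v$pos[i])
    if (d < 1 || d > 20000) next
    r2 <- pairwise_r2(sim$panel$calls[, i], sim$panel$calls[, j])
    if (is.na(r2)) next
    b <- ceiling(d / 500)
    agg[b, 1] <- agg[b, 1] + r2
    agg[b, 2] <- agg[b, 2] + 1
  }
  expect_equal(prof$n_pairs, as.integer(agg[, 2]))
  defined <- agg[, 2] > 0
  expect_equal(prof$mean_r2[defined], agg[defined, 1] / agg[defined, 2],
               tolerance = 1e-12)
  # copying-process LD decays with distance
  expect_gt(mean(prof$mean_r2[1:5], na.rm = TRUE),
            mean(prof$mean_r2[30:40], na.rm = TRUE))
})

decay_profile <- function(beta0, beta1, noise_sd = 0) {
  mid <- (1:40 - 0.5) * 500
  data.frame(bin = 1:40, midpoint = mid,
             mean_r2 = beta0 + beta1 / log(mid) +
               if (noise_sd > 0) rnorm(40, 0, noise_sd) else 0,
             se_r2 = NA, n_pairs = 100L)
}

test_that("the decay fit recovers coefficients exactly on noiseless data", {
  fit <- fit_decay(decay_profile(-0.40, 4.76))
  expect_equal(fit$beta0, -0.40, tolerance = 1e-10)
  expect_equal(fit$beta1, 4.76, tolerance = 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # flat profile: beta1 = 0, beta0 = the constant
  flat <- fit_decay(decay_profile(0.07, 0))
  expect_equal(flat$beta1, 0, tolerance = 1e-12)
  expect_equal(flat$beta0, 0.07, tolerance = 1e-12)
})

test_that("noisy fits equal the normal-equations solution and ignore bin order", {
  set.seed(72)
  prof <- decay_profile(-0.40, 4.76, noise_sd = 0.01)
  fit <- fit_decay(prof)
  z <- 1 / log(prof$midpoint)
  A <- cbind(1, z)
  beta <- solve(t(A) %*% A, t(A) %*% prof$mean_r2)
  expect_equal(fit$beta0, beta[1], tolerance = 1e-9)
  expect_equal(fit$beta1, beta[2], tolerance = 1e-9)
  shuf <- prof[sample(nrow(prof)), ]
  fit2 <- fit_decay(shuf)
  expect_equal(fit2$beta0, fit$beta0, tolerance = 1e-12)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-12)
})

test_that("threshold crossing inverts the fitted curve", {
  fit <- fit_decay(decay_profile(-0.40, 4.76))
  x <- solve_crossing(fit, 0.1)
  expect_equal(x, exp(4.76 / 0.5), tolerance = 1e-6)
  expect_equal(predict_decay(fit, x), 0.1, tolerance = 1e-9)
  # inversion identity at x = 2
  thr <- fit$beta0 + fit$beta1 / log(2)
  expect_equal(solve_crossing(fit, thr), 2, tolerance = 1e-6)
  expect_error(solve_crossing(fit, -0.5), "asymptote")
  # the lower-band crossing is closer than the point estimate
  set.seed(73)
  nf <- fit_decay(decay_profile(-0.40, 4.76, noise_sd = 0.005))
  xb <- solve_crossing(nf, 0.1, use_lower_band = TRUE)
  expect_lt(xb, solve_crossing(nf, 0.1))
  expect_gt(xb, 0)
})

test_that("greedy pruning removes linked markers within the window", {
  v <- rep(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L), 3)
  # two identical SNPs 1 kb apart: the second must go
  p <- toy_panel(cbind(v, v), pos = c(1000L, 2000L))
  expect_equal(prune_ld(p, window = 14000, r2_max = 0.1)$keep, 1)
  # independent SNPs are all retained
  set.seed(74)
  X <- matrix(sample(0:2, 120 * 6, TRUE), 120)
  stopifnot(max(cor(X)[upper.tri(cor(X))]^2) < 0.3)
  p2 <- toy_panel(X, pos = seq(1000L, by = 2000L, length.out = 6))
  expect_equal(prune_ld(p2, window = 14000, r2_max = 0.3)$keep, 1:6)
  # window limits the comparison range: identical SNPs 15 kb apart survive
  p3 <- toy_panel(cbind(v, v), pos = c(1000L, 16000L))
  expect_equal(prune_ld(p3, window = 14000, r2_max = 0.1)$keep, c(1, 2))
})

test_that("pruning matches an independent greedy evaluation on a chain", {
  a <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  b <- c(0, 1, 1, 2, 2, 0, 0, 1, 2, 2)
  cc <- c(2, 1, 0, 2, 2, 1, 0, 1, 0, 2)
  X <- cbind(a, b, cc)
  p <- toy_panel(X, pos = c(1000L, 2000L, 3000L))
  res <- prune_ld(p, window = 14000, r2_max = 0.1)
  # oracle: literal greedy scan with pairwise_r2
  retained <- 1
  for (j in 2:3) {
    r2s <- sapply(retained, function(k) cor(X[, j], X[, k])^2)
    if (all(r2s <= 0.1)) retained <- c(retained, j)
  }
  expect_equal(res$keep, retained)
})

test_that("after pruning no retained within-window pair exceeds the threshold", {
  sim <- small_panel(n_subpops = 1, samples_per_subpop = 50, n_snps = 120,
                     mean_depth = 30, n_scaffolds = 2,
                     scaffold_length = 50000, ld_rate = 1e-4, seed = 75)
  keep <- prune_ld(sim$panel, window = 14000, r2_max = 0.1)$keep
  v <- sim$panel$variants[keep, ]
  worst <- 0
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (i >= j || v$scaffold[i] != v$scaffold[j]) next
    if (abs(v$pos[i] - v$pos[j]) > 14000) next
    r2 <- pairwise_r2(sim$panel$calls[, keep[i]], sim$panel$calls[, keep[j]])
    if (!is.na(r2)) worst <- max(worst, r2)
  }
  expect_lte(worst, 0.1)
})
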