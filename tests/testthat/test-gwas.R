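test_that("stratified allele tables match a hand tally", {
  # 6 samples, 2 strata; dosage = alt-allele count
  calls <- matrix(c(2L, 1L, 0L, 1L, NA, 2L), 6, 1)
  strata <- c("A", "A", "A", "B", "B", "B")
  cases <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  tabs <- build_tables(calls, cases, strata)
  # stratum A cases: dosages 2,0 -> ref 2, alt 2; controls: dosage 1
  expect_equal(unname(tabs$a["A", 1]), 2)
  expect_equal(unname(tabs$b["A", 1]), 2)
  expect_equal(unname(tabs$c["A", 1]), 1)
  expect_equal(unname(tabs$d["A", 1]), 1)
  # stratum B cases: dosage 1 plus one missing -> 1 ref, 1 alt
  expect_equal(unname(tabs$a["B", 1]), 1)
  expect_equal(unname(tabs$b["B", 1]), 1)
  # controls: dosage 2 -> 0 ref, 2 alt
  expect_equal(unname(tabs$c["B", 1]), 0)
  expect_equal(unname(tabs$d["B", 1]), 2)
  # a lone alt-homozygous case contributes two alt alleles
  t1 <- build_tables(matrix(2L, 1, 1), TRUE, "A")
  expect_equal(unname(t1$b["A", 1]), 2)
  expect_equal(unname(t1$a["A", 1]), 0)
  expect_error(build_tables(calls, c(cases[-1], NA), strata), "phenotype")
})

test_that("the continuity-corrected CMH statistic matches hand evaluation", {
  one <- cmh_test(data.frame(a = 10, b = 5, c = 5, d = 10))
  expect_equal(one$chi2, (abs(10 - 7.5) - 0.5)^2 /
                 (15 * 15 * 15 * 15 / (30^3 - 30^2)), tolerance = 1e-12)
  expect_equal(one$chi2, 2.0622, tolerance = 1e-4)
  # two identical strata
  two <- cmh_test(data.frame(a = c(10, 10), b = c(5, 5),
                             c = c(5, 5), d = c(10, 10)))
  expect_equal(two$chi2, (5 - 0.5)^2 /
                 (2 * 15^4 / (30^3 - 30^2)), tolerance = 1e-12)
  expect_equal(two$chi2, 5.22, tolerance = 1e-3)
  # zero deviation: the floored correction cannot push past zero
  bal <- cmh_test(data.frame(a = 5, b = 5, c = 5, d = 5))
  expect_equal(bal$chi2, 0, tolerance = 1e-12)
  # all-degenerate strata are undefined
  expect_true(is.na(cmh_test(data.frame(a = 1, b = 0, c = 0, d = 0))$chi2))
})

test_that("CMH agrees with the stats-package oracle on random strata", {
  set.seed(91)
  for (i in 1:200) {
    K <- sample(2:4, 1)
    counts <- matrix(rpois(4 * K, 8) + 1, K, 4)
    tb <- data.frame(a = counts[, 1], b = counts[, 2],
                     c = counts[, 3], d = counts[, 4])
    arr <- array(0, c(2, 2, K))
    arr[1, 1, ] <- tb$a; arr[1, 2, ] <- tb$b
    arr[2, 1, ] <- tb$c; arr[2, 2, ] <- tb$d
    ref <- mantelhaen.test(arr, correct = TRUE)
    mine <- cmh_test(tb)
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
    # and with the correction disabled
    ref0 <- mantelhaen.test(arr, correct = FALSE)
    expect_equal(cmh_test(tb, correct = FALSE)$chi2,
                 unname(ref0$statistic), tolerance = 1e-6)
  }
})

test_that("BH adjustment equals the literal step-up definition", {
  expect_equal(fdr_bh(0.02), 0.02)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  set.seed(92)
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  for (len in 1:6) for (rep in 1:20) {
    p <- sample(grid, len, replace = TRUE)
    expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone in p and never smaller than p
  p <- runif(30)
  q <- fdr_bh(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("gene adjacency reports distances within the window", {
  genes <- data.frame(
    scaffold = c("sc929", "sc1945", "sc1945", "sc1945"),
    name = c("retinal degeneration C protein", "timeout/timeless-2",
             "transmembrane protein 53-B", "alkB homolog"),
    start = c(15781, 10017, 15487, 21608),
    end = c(45295, 14540, 16608, 22713), stringsAsFactors = FALSE)
  snps <- data.frame(scaffold = c("sc929", "sc1945"),
                     pos = c(14323, 12409), stringsAsFactors = FALSE)
  ann <- annotate_adjacent_genes(snps, genes, max_dist = 10000)
  # SNP 1.46 kb upstream of the gene start (15781 - 14323)
  expect_equal(ann[["sc929:14323"]]$distance, 1458)
  # SNP inside the gene body: distance 0; genes sorted by distance
  hit <- ann[["sc1945:12409"]]
  expect_equal(hit$distance[1], 0)
  expect_equal(hit$gene[1], "timeout/timeless-2")
  expect_true("alkB homolog" %in% hit$gene)
  expect_equal(hit$distance[hit$gene == "alkB homolog"], 9199)
  # the tighter 5-kb window drops the 9.2-kb neighbour
  ann5 <- annotate_adjacent_genes(snps, genes, max_dist = 5000)
  expect_false("alkB homolog" %in% ann5[["sc1945:12409"]]$gene)
  # malformed records are skipped with a warning
  genes$start[4] <- 99999
  expect_warning(res <- annotate_adjacent_genes(snps, genes), "malformed")
  expect_equal(attr(res, "n_skipped"), 1)
})

test_that("capture times map onto the dusk/dawn dichotomy", {
  expect_equal(classify_capture_window(c("18:00", "21:59", "02:00",
                                         "05:30", "23:00", "12:00")),
               c("dusk", "dusk", "dawn", "dawn", NA, NA))
})

test_that("a planted association dominates the genome-wide scan", {
  sim <- small_panel(n_subpops = 3, samples_per_subpop = c(40, 40, 40),
                     n_snps = 400, divergence_F = 0.01, mean_depth = 30,
                     n_causal = 3, causal_effect = 0.45,
                     causal_phenotype = "indoor_outdoor", seed = 93)
  res <- run_gwas(sim$panel, "indoor_outdoor")
  top <- order(res$p)[1:5]
  expect_true(all(sim$truth$causal_snps$index %in% top))
  expect_s3_class(res, "gwas_result")
  expect_true(all(c("scaffold", "pos", "ref", "alt", "chi2", "p",
                    "p_fdr", "significant") %in% names(res)))
  mt <- manhattan_table(res)
  expect_equal(mt$neglog10_p, -log10(res$p))
})

test_that("the scan attaches adjacent genes to significant SNPs", {
  sim <- small_panel(n_subpops = 2, samples_per_subpop = c(50, 50),
                     n_snps = 200, divergence_F = 0, mean_depth = 30,
                     n_causal = 2, causal_effect = 0.5, seed = 94)
  v <- sim$panel$variants[sim$truth$causal_snps$index, ]
  genes <- data.frame(scaffold = v$scaffold, name = paste0("gene", 1:2),
                      start = pmax(v$pos - 500, 1), end = v$pos + 500,
                      stringsAsFactors = FALSE)
  res <- run_gwas(sim$panel, "indoor_outdoor", genes = genes)
  expect_true(any(res$significant))
  ann <- attr(res, "adjacent_genes")
  expect_false(is.null(ann))
  sig_ids <- paste(res$scaffold[res$significant],
                   res$pos[res$significant], sep = ":")
  expect_setequal(names(ann), sig_ids)
})
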