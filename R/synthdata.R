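#' Configuration for the stratified low-coverage panel simulator
#'
#' Defaults mirror the study design the simulator emulates: three
#' collection-point strata in a single municipality with sample sizes
#' 95/60/166, microgeographic divergence on the order of FST 0.002,
#' ancestral minor-allele frequencies above the 0.1 working threshold,
#' and extreme low-coverage sequencing (mean depth 3 reads) with a 1%
#' per-read base error.
#'
#' @param n_subpops number of subpopulations (one per collection site).
#' @param samples_per_subpop integer vector of per-subpopulation sample
#'   counts (recycled to `n_subpops`).
#' @param n_snps number of biallelic SNPs.
#' @param divergence_F Balding--Nichols divergence parameter in \[0, 1):
#'   subpopulation allele frequencies are Beta-distributed around the
#'   ancestral frequency with variance `F * p * (1 - p)`.
#' @param ancestral_maf_range range (within (0, 0.5\]) from which ancestral
#'   alternative-allele frequencies are drawn uniformly.
#' @param mean_depth Poisson rate for per-genotype read depth.
#' @param base_error per-read probability of reading the wrong allele,
#'   in (0, 0.5).
#' @param n_causal number of SNPs carrying a planted phenotype
#'   association.
#' @param causal_effect allele-frequency difference between cases and
#'   controls within each stratum at causal SNPs (applied symmetrically,
#'   +/- `causal_effect / 2`).
#' @param causal_phenotype which dichotomy carries the planted effect.
#' @param phenotype_balance fraction of cases within each stratum.
#' @param n_scaffolds number of synthetic scaffolds.
#' @param scaffold_length scaffold length in base pairs; SNP positions
#'   are uniform within scaffolds, so all 40 LD distance bins up to
#'   20 kb are populated at the default density.
#' @param ld_rate optional per-base-pair haplotype copying decay rate.
#'   When set, adjacent alleles on a scaffold are copied from the
#'   previous SNP's allele with probability `exp(-ld_rate * distance)`,
#'   planting distance-decaying LD. Default `NULL` (independent SNPs).
#' @param seed integer seed for the simulator's single random stream.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subpops = 3,
                       samples_per_subpop = c(95, 60, 166),
                       n_snps = 5000,
                       divergence_F = 0.002,
                       ancestral_maf_range = c(0.1, 0.5),
                       mean_depth = 3,
                       base_error = 0.01,
                       n_causal = 0,
                       causal_effect = 0.2,
                       causal_phenotype = c("indoor_outdoor", "dusk_dawn"),
                       phenotype_balance = 0.5,
                       n_scaffolds = 20,
                       scaffold_length = 1e6,
                       ld_rate = NULL,
                       seed = 1) {
  causal_phenotype <- match.arg(causal_phenotype)
  samples_per_subpop <- rep_len(as.integer(samples_per_subpop), n_subpops)
  stopifnot(n_subpops >= 1, all(samples_per_subpop >= 1), n_snps >= 1,
            n_causal >= 0, n_causal <= n_snps,
            divergence_F >= 0, divergence_F < 1,
            base_error > 0, base_error < 0.5,
            mean_depth > 0,
            length(ancestral_maf_range) == 2,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            ancestral_maf_range[1] <= ancestral_maf_range[2],
            phenotype_balance > 0, phenotype_balance < 1,
            n_scaffolds >= 1, scaffold_length > 0)
  structure(list(n_subpops = n_subpops,
                 samples_per_subpop = samples_per_subpop,
                 n_snps = as.integer(n_snps),
                 divergence_F = divergence_F,
                 ancestral_maf_range = ancestral_maf_range,
                 mean_depth = mean_depth, base_error = base_error,
                 n_causal = as.integer(n_causal),
                 causal_effect = causal_effect,
                 causal_phenotype = causal_phenotype,
                 phenotype_balance = phenotype_balance,
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = scaffold_length,
                 ld_rate = ld_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw subpopulation allele frequencies under the Balding--Nichols model
#'
#' Each subpopulation frequency is Beta-distributed with mean equal to
#' the ancestral frequency `p` and variance `F * p * (1 - p)`
#' (shape parameters `p (1 - F) / F` and `(1 - p)(1 - F) / F`).
#' `F = 0` degenerates to the ancestral frequencies exactly.
#'
#' @param ancestral_freqs vector of per-SNP ancestral alternative-allele
#'   frequencies, each in (0, 1).
#' @param F divergence parameter in \[0, 1).
#' @param n_subpops number of subpopulations.
#' @param seed optional seed; `NULL` uses the current random stream.
#' @return `n_subpops x n_snps` matrix of frequencies.
#' @export
draw_subpop_frequencies <- function(ancestral_freqs, F, n_subpops,
                                    seed = NULL) {
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- length(ancestral_freqs)
  if (F == 0)
    return(matrix(ancestral_freqs, n_subpops, m, byrow = TRUE))
  ratio <- (1 - F) / F
  p <- rep(ancestral_freqs, each = n_subpops)
  matrix(stats::rbeta(n_subpops * m, p * ratio, (1 - p) * ratio),
         n_subpops, m)
}

#' Simulate a stratified low-coverage genotype panel with truth sidecar
#'
#' Genotypes are drawn in Hardy--Weinberg proportions within each
#' subpopulation from Balding--Nichols subpopulation frequencies.
#' Per-genotype read depth is Poisson(`mean_depth`); alternative-allele
#' read counts are binomial with allele probability `base_error`, 0.5 or
#' `1 - base_error` for true dosage 0, 1, 2. PL entries are rescaled
#' phred genotype likelihoods (minimum 0, as in VCF), `GQ` is the gap
#' between the two smallest PL entries, `DP` the total read count, and
#' the genotype call the likelihood-maximizing genotype. Genotypes with
#' zero reads carry a flat PL and are emitted as missing rather than by
#' an arbitrary tie-break.
#'
#' At causal SNPs the allele frequency is shifted by
#' `+/- causal_effect / 2` for cases/controls within every stratum of
#' the designated phenotype (clipped to \[0.01, 0.99\]).
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and
#'   `truth` (subpopulation frequencies, true dosages, causal SNP table
#'   and per-sample phenotype labels).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  K <- config$n_subpops
  n <- sum(config$samples_per_subpop)
  subpop <- rep(seq_len(K), config$samples_per_subpop)

  anc <- stats::runif(m, config$ancestral_maf_range[1],
                      config$ancestral_maf_range[2])
  freqs <- draw_subpop_frequencies(anc, config$divergence_F, K)

  # synthetic scaffolds with uniform, sorted, distinct positions
  scaf_of <- sort(rep_len(seq_len(config$n_scaffolds), m))
  pos <- integer(m)
  for (s in unique(scaf_of)) {
    idx <- which(scaf_of == s)
    pos[idx] <- sort(sample.int(config$scaffold_length, length(idx)))
  }
  variants <- data.frame(scaffold = sprintf("scaffold_%03d", scaf_of),
                         pos = pos,
                         ref = sample(c("A", "C", "G", "T"), m, TRUE),
                         alt = NA_character_, stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")

  sites <- LETTERS[subpop]
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    site = sites,
    stage = "adult",
    stringsAsFactors = FALSE)
  balanced_cases <- function() {
    lab <- character(n)
    for (s in unique(sites)) {
      idx <- which(sites == s)
      k <- round(config$phenotype_balance * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      lab[idx] <- "control"
      lab[sample(idx, k)] <- "case"
    }
    lab
  }
  io <- balanced_cases()
  dd <- balanced_cases()
  samples$indoor_outdoor <- ifelse(io == "case", "indoor", "outdoor")
  samples$capture_window <- ifelse(dd == "case", "dusk", "dawn")

  causal <- if (config$n_causal > 0) sort(sample.int(m, config$n_causal))
            else integer(0)
  case_vec <- if (config$causal_phenotype == "indoor_outdoor")
    io == "case" else dd == "case"

  # per-sample per-SNP frequency, with the causal shift where it applies
  pmat <- freqs[subpop, , drop = FALSE]
  if (length(causal)) {
    shift <- ifelse(case_vec, config$causal_effect / 2,
                    -config$causal_effect / 2)
    pmat[, causal] <- pmin(pmax(pmat[, causal] + shift, 0.01), 0.99)
  }

  if (is.null(config$ld_rate)) {
    geno <- matrix(stats::rbinom(n * m, 2L, pmat), n, m)
  } else {
    # first-order copying process along each scaffold: allele k copied
    # from allele k-1 with probability exp(-rate * distance)
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh1 <- stats::rbinom(n, 1L, pmat[, j])
      fresh2 <- stats::rbinom(n, 1L, pmat[, j])
      if (j > 1L && scaf_of[j] == scaf_of[j - 1L]) {
        rho <- exp(-config$ld_rate * (pos[j] - pos[j - 1L]))
        cp1 <- stats::runif(n) < rho
        cp2 <- stats::runif(n) < rho
        h1[, j] <- ifelse(cp1, h1[, j - 1L], fresh1)
        h2[, j] <- ifelse(cp2, h2[, j - 1L], fresh2)
      } else {
        h1[, j] <- fresh1; h2[, j] <- fresh2
      }
    }
    geno <- h1 + h2
  }

  dp <- matrix(stats::rpois(n * m, config$mean_depth), n, m)
  perr <- c(config$base_error, 0.5, 1 - config$base_error)
  alt_reads <- matrix(stats::rbinom(n * m, dp, perr[geno + 1L]), n, m)

  ll <- lapply(perr, function(pa)
    stats::dbinom(alt_reads, dp, pa, log = TRUE) / log(10))
  llmax <- pmax(ll[[1]], ll[[2]], ll[[3]])
  pl <- array(0, c(n, m, 3))
  for (k in 1:3) pl[, , k] <- round(-10 * (ll[[k]] - llmax))
  call_idx <- max.col(cbind(as.vector(ll[[1]]), as.vector(ll[[2]]),
                            as.vector(ll[[3]])), ties.method = "first")
  calls <- matrix(call_idx - 1L, n, m)
  calls[dp == 0L] <- NA_integer_
  gq <- pl[, , 1] + pl[, , 2] + pl[, , 3] -
    pmax(pl[, , 1], pl[, , 2], pl[, , 3])

  panel <- genotype_panel(calls, variants, samples,
                          dp = dp, gq = gq, pl = pl)
  truth <- list(subpop_freqs = freqs,
                true_genotypes = geno,
                causal_snps = data.frame(
                  index = causal,
                  phenotype = rep(config$causal_phenotype, length(causal)),
                  effect = rep(config$causal_effect, length(causal))),
                phenotype_labels = data.frame(
                  sample_id = samples$sample_id,
                  indoor_outdoor = io, dusk_dawn = dd,
                  stringsAsFactors = FALSE))
  list(panel = panel, truth = truth)
}

#' Write the simulation truth sidecar to TSV
#'
#' One row per SNP: id, per-subpopulation alternative-allele frequency
#' and a causal flag.
#'
#' @param truth the `truth` element returned by [simulate_panel()].
#' @param panel the matching panel (for SNP ids).
#' @param path output TSV path.
#' @export
write_truth_tsv <- function(truth, panel, path) {
  fr <- t(truth$subpop_freqs)
  colnames(fr) <- paste0("freq_subpop", seq_len(ncol(fr)))
  df <- data.frame(snp = colnames(panel$calls), fr,
                   causal = seq_len(nrow(fr)) %in% truth$causal_snps$index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
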