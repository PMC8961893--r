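#' Per-SNP stratified 2x2xK allele-count tables
#'
#' Every non-missing genotype contributes two alleles to its stratum's
#' table; a heterozygote contributes one allele to each column. Allele
#' "A" is the reference allele (the Cochran--Mantel--Haenszel statistic
#' is symmetric in this choice). Per stratum, `a`/`b` count reference/
#' alternative alleles in cases and `c`/`d` the same in controls.
#'
#' @param panel a `genotype_panel` or dosage matrix.
#' @param phenotype logical vector (`TRUE` = case) or a vector coercible
#'   to one via `== "case"`.
#' @param strata per-sample stratum labels (collection sites).
#' @return A `stratified_tables` list of `K x m` count matrices
#'   `a`, `b`, `c`, `d` plus the stratum labels.
#' @export
build_tables <- function(panel, phenotype, strata) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else
    as.matrix(panel)
  if (!is.logical(phenotype)) phenotype <- phenotype == "case"
  n <- nrow(calls)
  stopifnot(length(phenotype) == n, length(strata) == n)
  if (anyNA(phenotype) || anyNA(strata))
    stop("every sample needs a phenotype and a stratum")
  labs <- sort(unique(as.character(strata)))
  m <- ncol(calls)
  cnt <- function(rows) {
    sub <- calls[rows, , drop = FALSE]
    nn <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    rbind(ref = 2 * nn - alt, alt = alt)
  }
  a <- b <- cc <- d <- matrix(0, length(labs), m,
                              dimnames = list(labs, colnames(calls)))
  for (i in seq_along(labs)) {
    in_s <- strata == labs[i]
    case_cnt <- cnt(in_s & phenotype)
    ctrl_cnt <- cnt(in_s & !phenotype)
    a[i, ] <- case_cnt["ref", ]; b[i, ] <- case_cnt["alt", ]
    cc[i, ] <- ctrl_cnt["ref", ]; d[i, ] <- ctrl_cnt["alt", ]
  }
  structure(list(a = a, b = b, c = cc, d = d, strata = labs),
            class = "stratified_tables")
}

# vectorized continuity-corrected CMH over K x m count matrices
cmh_stat <- function(a, b, c, d, correct = TRUE) {
  n <- a + b + c + d
  ok <- n > 1
  num_i <- ifelse(ok, a - (a + b) * (a + c) / n, 0)
  var_i <- ifelse(ok, (a + b) * (a + c) * (b + d) * (c + d) /
                    (n^3 - n^2), 0)
  dev <- abs(colSums(rbind(num_i)))
  # Yates-style guard: the 1/2 correction is only applied when the summed
  # deviation reaches 1/2, so the statistic equals the printed formula for
  # every non-null table and is never pushed past zero on near-null ones
  num <- if (correct) dev - ifelse(dev >= 0.5, 0.5, 0) else dev
  den <- colSums(rbind(var_i))
  chi2 <- ifelse(den > 0, num^2 / den, NA_real_)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Continuity-corrected Cochran--Mantel--Haenszel test
#'
#' For a 2x2xK stratified allele-count table the statistic is
#' \deqn{\chi^2_{MH} = \frac{(|\sum_i a_i - (a_i+b_i)(a_i+c_i)/n_i| -
#'   1/2)^2}{\sum_i (a_i+b_i)(a_i+c_i)(b_i+d_i)(c_i+d_i) /
#'   (n_i^3 - n_i^2)}}{chi2 = (|sum(a - (a+b)(a+c)/n)| - 1/2)^2 /
#'   sum((a+b)(a+c)(b+d)(c+d)/(n^3 - n^2))}
#' referred to a chi-square distribution with one degree of freedom.
#' Strata with `n <= 1` contribute zero to both sums (zero-variance
#' strata contribute zero naturally through their margins). The 1/2
#' continuity correction is applied by default; `correct = FALSE`
#' disables it for cross-checks against uncorrected references.
#'
#' @param tables a `stratified_tables` (single-SNP columns are fine),
#'   a 2x2xK array (rows = case/control, columns = allele A/B), or a
#'   data.frame/matrix with columns `a`, `b`, `c`, `d` (rows = strata).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return For a single table set, list with `chi2` and `p`; for a
#'   multi-SNP `stratified_tables`, vectors over SNPs. `NA` when all
#'   strata are degenerate.
#' @export
cmh_test <- function(tables, correct = TRUE) {
  if (inherits(tables, "stratified_tables"))
    return(cmh_stat(tables$a, tables$b, tables$c, tables$d, correct))
  if (is.array(tables) && length(dim(tables)) == 3) {
    a <- tables[1, 1, ]; b <- tables[1, 2, ]
    cc <- tables[2, 1, ]; d <- tables[2, 2, ]
  } else {
    tb <- as.data.frame(tables)
    stopifnot(all(c("a", "b", "c", "d") %in% names(tb)))
    a <- tb$a; b <- tb$b; cc <- tb$c; d <- tb$d
  }
  res <- cmh_stat(cbind(a), cbind(b), cbind(cc), cbind(d), correct)
  list(chi2 = unname(res$chi2[1]), p = unname(res$p[1]))
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1 and monotone-enforced, in
#' the input order (a thin validating wrapper over
#' `p.adjust(method = "BH")`).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_bh <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Genes adjacent to SNPs within a physical window
#'
#' Distance is 0 for a SNP inside a gene's `[start, end]` interval and
#' otherwise the distance to the nearer interval end. Genes on the same
#' scaffold within `max_dist` are reported sorted by distance.
#'
#' @param snps data.frame with columns `scaffold` and `pos`.
#' @param genes data.frame with columns `scaffold`, `name`, `start`,
#'   `end` (1-based inclusive), e.g. from [read_gff_genes()]. Records
#'   with `start > end` or missing coordinates are skipped; their count
#'   is attached as attribute `n_skipped` (with a warning).
#' @param max_dist maximum distance in bp (default 10 kb; set 5000 for
#'   the stricter 5-kb-each-way reading).
#' @return Named list (one element per SNP, `scaffold:pos`) of
#'   data.frames `gene`, `start`, `end`, `distance`.
#' @export
annotate_adjacent_genes <- function(snps, genes, max_dist = 10000) {
  stopifnot(all(c("scaffold", "pos") %in% names(snps)),
            all(c("scaffold", "name", "start", "end") %in% names(genes)))
  bad <- is.na(genes$start) | is.na(genes$end) | genes$start > genes$end
  if (any(bad)) {
    warning(sum(bad), " malformed gene record(s) skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  out <- vector("list", nrow(snps))
  names(out) <- paste(snps$scaffold, snps$pos, sep = ":")
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$scaffold == snps$scaffold[i], , drop = FALSE]
    pos <- snps$pos[i]
    dist <- ifelse(pos >= g$start & pos <= g$end, 0,
                   pmin(abs(pos - g$start), abs(pos - g$end)))
    keep <- dist <= max_dist
    g <- g[keep, , drop = FALSE]
    res <- data.frame(gene = g$name, start = g$start, end = g$end,
                      distance = dist[keep], stringsAsFactors = FALSE)
    out[[i]] <- res[order(res$distance), , drop = FALSE]
  }
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Extract gene intervals from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @param feature_types GFF3 `type` values treated as genes.
#' @return data.frame with `scaffold`, `name`, `start`, `end`. The gene
#'   name is taken from the `Name=` attribute, falling back to `ID=`.
#' @export
read_gff_genes <- function(path,
                           feature_types = c("gene",
                                             "protein_coding_gene")) {
  g <- ape::read.gff(path)
  g <- g[g$type %in% feature_types, , drop = FALSE]
  getattr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  nm <- getattr(g$attributes, "Name")
  nm[is.na(nm)] <- getattr(g$attributes, "ID")[is.na(nm)]
  data.frame(scaffold = as.character(g$seqid), name = nm,
             start = g$start, end = g$end, stringsAsFactors = FALSE)
}

#' Classify a capture time into the dusk/dawn dichotomy
#'
#' Dusk is 18:00--22:00 and dawn 02:00--06:00 (half-open on the right);
#' captures outside both windows return `NA`.
#'
#' @param times character vector of `"HH:MM"` clock times.
#' @return Character vector `"dusk"`/`"dawn"`/`NA`.
#' @export
classify_capture_window <- function(times) {
  hr <- as.numeric(sub(":.*", "", times)) +
    as.numeric(sub(".*:", "", times)) / 60
  ifelse(hr >= 18 & hr < 22, "dusk",
         ifelse(hr >= 2 & hr < 6, "dawn", NA_character_))
}

#' Stratified genome-wide association scan
#'
#' Runs the continuity-corrected CMH test at every SNP with collection
#' sites as strata, applies Benjamini--Hochberg FDR, and (when a gene
#' table is supplied) annotates FDR-significant SNPs with genes within
#' `gene_window` bp.
#'
#' @param panel a `genotype_panel` with metadata columns for the chosen
#'   phenotype (`indoor_outdoor`: case = indoor; `dusk_dawn`: case =
#'   dusk from `capture_window`).
#' @param phenotype `"indoor_outdoor"`, `"dusk_dawn"`, or an explicit
#'   logical case vector.
#' @param strata per-sample labels; defaults to the panel `site`.
#' @param fdr_alpha significance threshold on adjusted p-values.
#' @param genes optional gene table for [annotate_adjacent_genes()].
#' @param gene_window adjacency window in bp.
#' @param correct apply the 1/2 continuity correction.
#' @return A `gwas_result` data.frame with one row per SNP (`scaffold`,
#'   `pos`, `ref`, `alt`, `chi2`, `p`, `p_fdr`, `significant`) and,
#'   when genes were supplied, an `adjacent_genes` attribute for the
#'   significant rows.
#' @export
run_gwas <- function(panel, phenotype = c("indoor_outdoor", "dusk_dawn"),
                     strata = NULL, fdr_alpha = 0.05, genes = NULL,
                     gene_window = 10000, correct = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(phenotype) && length(phenotype) == 1) {
    phenotype <- match.arg(phenotype)
    pheno <- switch(phenotype,
      indoor_outdoor = panel$samples$indoor_outdoor == "indoor",
      dusk_dawn = panel$samples$capture_window == "dusk")
  } else pheno <- as.logical(phenotype)
  if (is.null(strata)) strata <- panel$samples$site
  keep <- !is.na(pheno) & !is.na(strata)
  tabs <- build_tables(panel[keep, ], pheno[keep], strata[keep])
  res <- cmh_test(tabs, correct = correct)
  ok <- !is.na(res$p)
  p_fdr <- rep(NA_real_, length(res$p))
  p_fdr[ok] <- fdr_bh(res$p[ok])
  out <- data.frame(panel$variants[, c("scaffold", "pos", "ref", "alt")],
                    chi2 = res$chi2, p = res$p, p_fdr = p_fdr,
                    significant = !is.na(p_fdr) & p_fdr < fdr_alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  if (!is.null(genes) && any(out$significant))
    attr(out, "adjacent_genes") <- annotate_adjacent_genes(
      out[out$significant, c("scaffold", "pos")], genes,
      max_dist = gene_window)
  out
}

#' Plot-ready Manhattan table
#'
#' @param result a `gwas_result`.
#' @return data.frame `scaffold`, `pos`, `neglog10_p`, `significant`.
#' @export
manhattan_table <- function(result) {
  data.frame(scaffold = result$scaffold, pos = result$pos,
             neglog10_p = -log10(result$p),
             significant = result$significant,
             stringsAsFactors = FALSE)
}
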