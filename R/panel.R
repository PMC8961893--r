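#' Genotype panel container
#'
#' A `genotype_panel` holds a samples-by-variants matrix of biallelic
#' genotype dosages (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternative, `NA` = missing) together with the
#' per-genotype sequencing evidence carried by low-coverage VCF panels:
#' read depth (`DP`), phred genotype quality (`GQ`), phred-scaled
#' normalized genotype likelihoods (`PL`, minimum entry 0) and, after
#' imputation, posterior genotype probabilities (`GP`).
#'
#' @param calls integer matrix, samples in rows, variants in columns;
#'   entries 0/1/2 or `NA`.
#' @param variants data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param samples data.frame with at least a `sample_id` column;
#'   typically also `site` (collection-point stratum), `stage`,
#'   `indoor_outdoor` and `capture_window`.
#' @param dp,gq integer matrices conformable with `calls`, or `NULL`.
#' @param pl numeric array `n_samples x n_variants x 3` of phred-scaled
#'   likelihoods ordered hom-ref, het, hom-alt (VCF order), or `NULL`.
#' @param gp numeric array like `pl` holding genotype posteriors, or `NULL`.
#' @param mask logical matrix flagging genotypes queued for imputation,
#'   or `NULL` if [mask_low_confidence()] has not been applied.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(calls, variants, samples,
                           dp = NULL, gq = NULL, pl = NULL, gp = NULL,
                           mask = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n <- nrow(calls)
  m <- ncol(calls)
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(variants) != m)
    stop("variants table has ", nrow(variants), " rows but calls has ", m,
         " columns")
  if (nrow(samples) != n)
    stop("samples table has ", nrow(samples), " rows but calls has ", n,
         " rows")
  if (!all(c("scaffold", "pos", "ref", "alt") %in% names(variants)))
    stop("variants must have columns scaffold, pos, ref, alt")
  if (!"sample_id" %in% names(samples))
    stop("samples must have a sample_id column")
  if (any(variants$pos <= 0)) stop("variant positions must be positive")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be dosages in {0,1,2} or NA")
  chk <- function(x, nm, dims = 2L) {
    if (is.null(x)) return(NULL)
    if (dims == 2L) {
      x <- as.matrix(x)
      if (!all(dim(x) == c(n, m))) stop(nm, " has wrong dimensions")
    } else {
      if (!is.array(x) || !all(dim(x) == c(n, m, 3)))
        stop(nm, " must be an n x m x 3 array")
    }
    x
  }
  dp <- chk(dp, "dp"); gq <- chk(gq, "gq")
  pl <- chk(pl, "pl", 3L); gp <- chk(gp, "gp", 3L)
  if (!is.null(mask)) {
    mask <- chk(mask, "mask")
    storage.mode(mask) <- "logical"
  }
  ids <- paste(variants$scaffold, variants$pos, sep = ":")
  dimnames(calls) <- list(samples$sample_id, ids)
  structure(list(calls = calls, variants = variants, samples = samples,
                 dp = dp, gq = gq, pl = pl, gp = gp, mask = mask),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$calls), "samples x", ncol(x$calls),
      "variants\n")
  cat("  genotyping rate:",
      format(round(genotyping_rate(x), 4)), "\n")
  cat("  fields:",
      paste(c("GT", "DP"[!is.null(x$dp)], "GQ"[!is.null(x$gq)],
              "PL"[!is.null(x$pl)], "GP"[!is.null(x$gp)]), collapse = ":"),
      if (!is.null(x$mask)) sprintf("(%d genotypes masked)", sum(x$mask)),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Subset a genotype panel by sample and/or variant index
#'
#' @param x a `genotype_panel`.
#' @param i sample index (logical, integer or character).
#' @param j variant index.
#' @param ... ignored.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  sub3 <- function(a) if (is.null(a)) NULL else a[i, j, , drop = FALSE]
  sub2 <- function(a) if (is.null(a)) NULL else a[i, j, drop = FALSE]
  genotype_panel(x$calls[i, j, drop = FALSE],
                 x$variants[j, , drop = FALSE],
                 x$samples[i, , drop = FALSE],
                 dp = sub2(x$dp), gq = sub2(x$gq),
                 pl = sub3(x$pl), gp = sub3(x$gp), mask = sub2(x$mask))
}

#' Fraction of non-missing genotype calls in a panel
#'
#' The genotyping rate is the proportion of sample-by-variant cells with
#' a called (non-missing) genotype.
#'
#' @param panel a `genotype_panel`.
#' @return A fraction in \[0, 1\].
#' @export
genotyping_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(panel$calls) == 0L) stop("empty panel")
  mean(!is.na(panel$calls))
}

gt_strings <- c("0/0", "0/1", "1/1")

#' Write a genotype panel to VCF 4.2
#'
#' Emits FORMAT fields `GT:DP:GQ:PL` (and `GP`, with 5 decimal places,
#' when posteriors are present), with contig header lines for every
#' scaffold. Output is gzip-compressed (as produced by
#' [vcfR::write.vcf()]); [read_panel_vcf()] reads it back.
#'
#' @param panel a `genotype_panel` carrying at least `dp`, `gq` and `pl`.
#' @param path output file path (conventionally ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$calls); m <- ncol(panel$calls)
  v <- panel$variants
  contigs <- unique(v$scaffold)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", contigs, ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
            "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">")
  has_gp <- !is.null(panel$gp)
  if (has_gp)
    meta <- c(meta,
              "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">")
  fix <- cbind(CHROM = as.character(v$scaffold),
               POS = as.character(v$pos),
               ID = colnames(panel$calls),
               REF = as.character(v$ref), ALT = as.character(v$alt),
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_chr <- matrix("./.", n, m)
  ok <- !is.na(panel$calls)
  gt_chr[ok] <- gt_strings[panel$calls[ok] + 1L]
  fmt <- paste0("GT:DP:GQ:PL", if (has_gp) ":GP")
  cell <- paste(gt_chr,
                if (is.null(panel$dp)) "." else panel$dp,
                if (is.null(panel$gq)) "." else panel$gq,
                if (is.null(panel$pl)) "." else
                  paste(panel$pl[, , 1], panel$pl[, , 2], panel$pl[, , 3],
                        sep = ","),
                sep = ":")
  if (has_gp)
    cell <- paste(cell,
                  paste(sprintf("%.5f", panel$gp[, , 1]),
                        sprintf("%.5f", panel$gp[, , 2]),
                        sprintf("%.5f", panel$gp[, , 3]), sep = ","),
                  sep = ":")
  gt <- matrix(cell, n, m)
  gtm <- cbind(FORMAT = fmt, t(gt))
  colnames(gtm) <- c("FORMAT", panel$samples$sample_id)
  vcf <- methods::new(methods::className("vcfR", "vcfR"),
                      meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

parse_triplet <- function(x, n, m) {
  # "a,b,c" strings (variants x samples, vcfR layout) -> n x m x 3 array
  parts <- strsplit(as.vector(x), ",", fixed = TRUE)
  num <- suppressWarnings(vapply(parts, function(p)
    if (length(p) == 3L) as.numeric(p) else rep(NA_real_, 3), numeric(3)))
  arr <- array(NA_real_, c(n, m, 3))
  for (k in 1:3) arr[, , k] <- t(matrix(num[k, ], nrow = m))
  arr
}

#' Read a VCF 4.2 file into a genotype panel
#'
#' Parses `GT`, `DP`, `GQ`, `PL` and (when present) `GP` FORMAT fields.
#' Multi-allelic records are dropped with a message, since every
#' statistic in this package is defined for biallelic SNPs.
#'
#' @param path VCF file (optionally gzipped).
#' @param metadata optional sample metadata data.frame (or TSV path) with
#'   a `sample_id` column, joined to the VCF sample columns.
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path, metadata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic record(s)")
    vcf <- vcf[!multi, ]
    fix <- vcfR::getFIX(vcf)
  }
  gt <- vcfR::extract.gt(vcf, "GT")
  m <- nrow(gt); n <- ncol(gt)
  dose <- matrix(NA_integer_, n, m)
  clean <- gsub("|", "/", t(gt), fixed = TRUE)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  num2 <- function(field) {
    x <- vcfR::extract.gt(vcf, field)
    if (all(is.na(x))) return(NULL)
    t(matrix(suppressWarnings(as.numeric(x)), nrow = m))
  }
  fmt <- vcf@gt[1, "FORMAT"]
  keys <- strsplit(fmt, ":", fixed = TRUE)[[1]]
  pl <- if ("PL" %in% keys) parse_triplet(vcfR::extract.gt(vcf, "PL"), n, m)
  gp <- if ("GP" %in% keys) parse_triplet(vcfR::extract.gt(vcf, "GP"), n, m)
  variants <- data.frame(scaffold = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (is.character(metadata))
      metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    idx <- match(samples$sample_id, metadata$sample_id)
    if (anyNA(idx))
      stop("metadata is missing sample(s): ",
           paste(samples$sample_id[is.na(idx)], collapse = ", "))
    samples <- metadata[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  genotype_panel(dose, variants, samples,
                 dp = num2("DP"), gq = num2("GQ"), pl = pl, gp = gp)
}

#' Write per-sample metadata to TSV
#'
#' @param panel a `genotype_panel`.
#' @param path output TSV path.
#' @export
write_sample_metadata <- function(panel, path) {
  utils::write.table(panel$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
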