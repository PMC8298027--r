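#' Genotype matrix container
#'
#' Samples-by-markers matrix of alternate-allele counts in \{0, 1, 2\}, with
#' `NA` for missing calls. After mean imputation, calls are real numbers in
#' \[0, 2\] and no missing entries remain.
#'
#' @param calls numeric matrix with sample ids as row names and marker ids as
#'   column names.
#' @param imputed logical; `TRUE` once missing calls have been replaced by
#'   per-marker means.
#' @return an object of class `geno_matrix` (a list with elements `calls` and
#'   `imputed`).
#' @export
geno_matrix <- function(calls, imputed = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids")
  if (length(calls) > 0 && !all(is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("genotype calls must lie in [0, 2]")
    if (!imputed && !all(calls[!is.na(calls)] %in% c(0, 1, 2)))
      stop("un-imputed calls must be 0, 1, 2 or missing")
    if (imputed && anyNA(calls))
      stop("imputed genotype matrix cannot contain missing calls")
  }
  structure(list(calls = calls, imputed = imputed), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " markers; ", sum(is.na(x$calls)), " missing calls",
      if (x$imputed) " (mean-imputed)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Sample and marker identifiers of a genotype matrix
#' @param gm a [geno_matrix()].
#' @return character vector of ids.
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' @rdname sample_ids
#' @export
marker_ids <- function(gm) colnames(gm$calls)

#' Read a genotype matrix from CSV or VCF
#'
#' The CSV dialect has the sample id in the first column and marker ids in the
#' header; missing tokens `NA`, `-` and the empty string are accepted and any
#' other unrecognized token is mapped to missing with a reported count. The
#' VCF dialect maps GT fields 0/0, 0/1 (or 1/0), 1/1, ./. to 0, 1, 2, missing.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"vcf"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("csv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", "-", ""))
    if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty genotype file: ", path)
    ids <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    vals <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                    dimnames = list(ids, colnames(m))))
    bad <- sum(is.na(vals)) - sum(is.na(m))
    if (bad > 0)
      message(bad, " unrecognized genotype token(s) mapped to missing")
    geno_matrix(vals)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
    vals <- matrix(map[gt], nrow(gt), ncol(gt))
    unknown <- sum(is.na(vals) & !is.na(gt) & gt != "./." & gt != ".|.")
    if (unknown > 0)
      message(unknown, " unrecognized GT value(s) mapped to missing")
    calls <- t(vals)
    dimnames(calls) <- list(colnames(gt), rownames(gt))
    geno_matrix(calls)
  }
}

#' Write a genotype matrix as CSV
#'
#' First column `sample_id`, one column per marker, missing written as `NA`.
#' Round-trips through [read_genotypes()].
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(sample_id = sample_ids(gm), gm$calls,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter markers on call rate
#'
#' Retains markers whose fraction of non-missing calls is at least
#' `threshold` (the 50% call-rate rule of the study, boundary inclusive),
#' preserving marker order. Optionally filters samples by the same rule.
#'
#' @param gm a [geno_matrix()].
#' @param threshold minimum call rate in (0, 1\].
#' @param samples if `TRUE`, additionally drop samples with call rate below
#'   `threshold` (off by default; the study filter is per-marker).
#' @return the filtered [geno_matrix()]. Removing every marker yields an
#'   empty matrix with a warning, not an error.
#' @export
call_rate_filter <- function(gm, threshold = 0.5, samples = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  cr <- colMeans(!is.na(gm$calls))
  keep <- cr >= threshold
  message("call_rate_filter: ", sum(keep), " of ", length(keep),
          " markers retained at call rate >= ", threshold)
  if (!any(keep)) warning("all markers removed by call-rate filter")
  calls <- gm$calls[, keep, drop = FALSE]
  if (samples) {
    scr <- rowMeans(!is.na(calls))
    skeep <- scr >= threshold
    message("call_rate_filter: ", sum(skeep), " of ", length(skeep),
            " samples retained")
    calls <- calls[skeep, , drop = FALSE]
  }
  geno_matrix(calls, imputed = gm$imputed)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call with the per-marker mean of the observed calls
#' (a real number in \[0, 2\]), the default imputation of the study's
#' analysis software. Allele frequencies are unchanged by this imputation
#' since the marker mean is preserved.
#'
#' @param gm a [geno_matrix()].
#' @return the imputed [geno_matrix()] with `imputed = TRUE`.
#' @export
impute_mean <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- gm$calls
  n_obs <- colSums(!is.na(calls))
  if (any(n_obs == 0))
    stop("marker(s) with zero non-missing calls: run call_rate_filter first (",
         paste(utils::head(colnames(calls)[n_obs == 0], 5), collapse = ", "),
         ")")
  mu <- colMeans(calls, na.rm = TRUE)
  miss <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(miss) > 0) calls[miss] <- mu[miss[, 2]]
  geno_matrix(calls, imputed = TRUE)
}

#' Per-marker alternate allele frequencies
#'
#' `p_j = sum(calls_j) / (2 * n_non_missing_j)`; `q_j = 1 - p_j`. Invariant to
#' sample order and to mean imputation.
#'
#' @param gm a [geno_matrix()].
#' @return named numeric vector of frequencies `p_j`.
#' @export
allele_frequencies <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  colMeans(gm$calls, na.rm = TRUE) / 2
}

#' Write hard genotype calls as VCF 4.2
#'
#' One record per marker with GT-only FORMAT. DArT tags are unplaced, so each
#' marker gets a synthetic contig `tag<k>` at POS 1. Imputed (fractional)
#' matrices cannot be serialized: VCF carries hard calls, missing stays `./.`.
#'
#' @param gm an un-imputed [geno_matrix()].
#' @param path output path.
#' @export
to_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (gm$imputed || !all(gm$calls[!is.na(gm$calls)] %in% c(0, 1, 2)))
    stop("to_vcf requires hard (un-imputed) calls in {0, 1, 2, missing}")
  n <- nrow(gm$calls); m <- ncol(gm$calls)
  gt_map <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=tag", seq_len(m), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t"))
  gts <- matrix("./.", m, n)
  obs <- !is.na(t(gm$calls))
  gts[obs] <- gt_map[t(gm$calls)[obs] + 1]
  records <- paste(paste0("tag", seq_len(m)), 1, marker_ids(gm), "A", "G",
                   ".", "PASS", ".", "GT",
                   apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}
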