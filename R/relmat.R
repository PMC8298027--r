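#' Relationship matrix container
#'
#' A symmetric numeric matrix with sample ids as dimnames and a `kind`
#' attribute (`"G_vanraden"`, `"G_gcta"` or `"A"`). VanRaden matrices also
#' carry their scaling constant `sum(2 p q)`.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param kind one of `"G_vanraden"`, `"G_gcta"`, `"A"`.
#' @param scaling optional scaling constant.
#' @return an object of class `relmat` (a matrix).
#' @export
relmat <- function(values, kind, scaling = NULL) {
  values <- as.matrix(values)
  if (max(abs(values - t(values))) > 1e-10)
    stop("relationship matrix must be symmetric")
  values <- (values + t(values)) / 2
  structure(values, kind = kind, scaling = scaling,
            class = c("relmat", class(values)))
}

#' @export
print.relmat <- function(x, ...) {
  cat("Relationship matrix (", attr(x, "kind"), "): ", nrow(x), " x ",
      ncol(x), "; mean diagonal ", round(mean(diag(x)), 4), "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' `G = M M' / sum_j 2 p_j q_j` where `M` is the call matrix with each column
#' centered by twice its observed allele frequency. Requires an imputed (or
#' complete) genotype matrix.
#'
#' @param gm a [geno_matrix()] without missing calls.
#' @return a [relmat] of kind `"G_vanraden"` with the scaling constant
#'   attached as attribute `scaling`.
#' @export
grm_vanraden <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$calls))
    stop("genotype matrix contains missing calls: impute first")
  p <- allele_frequencies(gm)
  s2pq <- sum(2 * p * (1 - p))
  if (s2pq <= 0) stop("all markers monomorphic: sum(2pq) = 0")
  M <- sweep(gm$calls, 2, 2 * p)
  relmat(tcrossprod(M) / s2pq, kind = "G_vanraden", scaling = s2pq)
}

#' Per-marker standardized (GCTA-style) genomic relationship matrix
#'
#' Averages `(x_ij - 2 p_j)(x_kj - 2 p_j) / (2 p_j q_j)` over markers, i.e.
#' each marker is standardized before averaging. Monomorphic markers
#' (`p` of 0 or 1) are excluded with a message.
#'
#' @param gm a [geno_matrix()] without missing calls.
#' @return a [relmat] of kind `"G_gcta"`.
#' @export
grm_gcta <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (anyNA(gm$calls))
    stop("genotype matrix contains missing calls: impute first")
  p <- allele_frequencies(gm)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  if (any(!poly))
    message("grm_gcta: excluding ", sum(!poly), " monomorphic marker(s)")
  pp <- p[poly]
  Z <- sweep(gm$calls[, poly, drop = FALSE], 2, 2 * pp)
  Z <- sweep(Z, 2, sqrt(2 * pp * (1 - pp)), "/")
  relmat(tcrossprod(Z) / sum(poly), kind = "G_gcta")
}

#' Repair a near-singular relationship matrix
#'
#' If the smallest eigenvalue falls below `tol`, adds `bump` to the diagonal
#' (and reports it). Needed before inverting G for mixed-model equations and
#' allele-substitution back-solving.
#'
#' @param K a [relmat] or plain symmetric matrix.
#' @param tol eigenvalue threshold.
#' @param bump diagonal increment.
#' @return the (possibly bent) matrix.
#' @export
bend_psd <- function(K, tol = 1e-8, bump = 1e-6) {
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < tol) {
    message("bending relationship matrix: min eigenvalue ",
            format(ev_min, digits = 3), ", adding ", bump, " to diagonal")
    K <- K + diag(bump, nrow(K))
  }
  K
}

#' Write a relationship matrix as CSV or sparse triplet text
#'
#' @param K a [relmat].
#' @param path output path.
#' @param format `"full"` (symmetric CSV with id header) or `"sparse"`
#'   (3-column i, j, value, lower triangle).
#' @export
write_relmat <- function(K, path, format = c("full", "sparse")) {
  format <- match.arg(format)
  if (format == "full") {
    df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = rownames(K)[idx[, 1]], j = colnames(K)[idx[, 2]],
                     value = K[idx])
    utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
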