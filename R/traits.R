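#' Meat-yield condition index
#'
#' `soft tissue weight * 100 / (whole weight - shell weight)`. Undefined
#' where whole weight does not exceed shell weight; such records are returned
#' as missing with a warning.
#'
#' @param soft soft tissue weight (g).
#' @param whole whole weight (g).
#' @param shell shell weight (g).
#' @return numeric vector of condition indices.
#' @export
condition_index <- function(soft, whole, shell) {
  out <- soft * 100 / (whole - shell)
  bad <- !is.na(whole) & !is.na(shell) & whole <= shell
  if (any(bad)) {
    warning(sum(bad), " record(s) with whole weight <= shell weight: ",
            "condition index set missing")
    out[bad] <- NA_real_
  }
  out
}

#' Shell shape ratios
#'
#' Cup ratio is shell width over shell depth; fan ratio is shell length over
#' shell depth. A non-positive depth yields missing with a warning.
#'
#' @param width,depth,length shell dimensions (mm).
#' @return numeric vector of ratios.
#' @export
cup_ratio <- function(width, depth) shape_ratio(width, depth)

#' @rdname cup_ratio
#' @export
fan_ratio <- function(length, depth) shape_ratio(length, depth)

shape_ratio <- function(num, depth) {
  out <- num / depth
  bad <- !is.na(depth) & depth <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive shell depth: ratio set ",
            "missing")
    out[bad] <- NA_real_
  }
  out
}

#' Add derived traits to a phenotype table
#'
#' Computes condition index (if `soft_tissue_weight`, `whole_weight` and
#' `shell_weight` are present) and cup/fan ratios (if `shell_width`,
#' `shell_length` and `shell_depth` are present).
#'
#' @param pt phenotype `data.frame`.
#' @return the table with added columns among `condition_index`, `cup_ratio`,
#'   `fan_ratio`.
#' @export
derive_traits <- function(pt) {
  if (all(c("soft_tissue_weight", "whole_weight", "shell_weight") %in%
          names(pt)))
    pt$condition_index <- condition_index(pt$soft_tissue_weight,
                                          pt$whole_weight, pt$shell_weight)
  if (all(c("shell_width", "shell_depth") %in% names(pt)))
    pt$cup_ratio <- cup_ratio(pt$shell_width, pt$shell_depth)
  if (all(c("shell_length", "shell_depth") %in% names(pt)))
    pt$fan_ratio <- fan_ratio(pt$shell_length, pt$shell_depth)
  pt
}

#' Build the fixed-effects design for one trait
#'
#' Restricts to samples with the trait observed and assembles a full-rank
#' fixed-effects matrix under treatment (reference-level) coding: intercept
#' (the overall mean of the animal model), generation and sex factors,
#' generation-by-sex interaction, and one age-covariate column per generation
#' (age nested within generation, centered within generation to reduce
#' collinearity). Single-level factors are absorbed into the intercept with a
#' warning; rank-deficient columns are dropped with a message.
#'
#' @param pt phenotype `data.frame` with columns `id` and the trait; optional
#'   `generation`, `sex`, `age` covariates.
#' @param trait trait column name.
#' @param full_interactions if `TRUE`, also fit sex-by-age interactions
#'   (nested within generation); default fits generation-by-sex only.
#' @return an object of class `design_matrix`: list with `y` (response), `X`
#'   (full-rank design), `ids` (sample id per row) and `trait`.
#' @export
build_design <- function(pt, trait, full_interactions = FALSE) {
  if (!trait %in% names(pt)) stop("trait not found: ", trait)
  keep <- !is.na(pt[[trait]])
  for (v in intersect(c("generation", "sex", "age"), names(pt)))
    keep <- keep & !is.na(pt[[v]])
  if (sum(keep) == 0L) stop("trait entirely missing: ", trait)
  if (sum(keep) < 2L) stop("fewer than 2 informative rows for ", trait)
  d <- pt[keep, , drop = FALSE]
  y <- d[[trait]]
  ids <- as.character(d$id)

  terms <- character(0)
  has <- function(v) v %in% names(d)
  usable_factor <- function(v) {
    if (!has(v)) return(FALSE)
    f <- factor(d[[v]])
    if (nlevels(f) < 2L) {
      warning("factor '", v, "' has a single level and is absorbed into ",
              "the intercept")
      return(FALSE)
    }
    TRUE
  }
  use_gen <- usable_factor("generation")
  use_sex <- usable_factor("sex")
  if (use_gen) d$generation <- factor(d$generation)
  if (use_sex) d$sex <- factor(d$sex)
  if (use_gen) terms <- c(terms, "generation")
  if (use_sex) terms <- c(terms, "sex")
  if (use_gen && use_sex) terms <- c(terms, "generation:sex")
  if (has("age")) {
    if (use_gen) {
      # center age within generation, one slope per generation
      d$age_c <- d$age - stats::ave(d$age, d$generation)
      terms <- c(terms, "generation:age_c")
      if (full_interactions && use_sex) terms <- c(terms, "sex:age_c")
    } else {
      d$age_c <- d$age - mean(d$age)
      terms <- c(terms, "age_c")
      if (full_interactions && use_sex) terms <- c(terms, "sex:age_c")
    }
  }
  fml <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  } else {
    ~1
  }
  X <- stats::model.matrix(fml, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    message("dropping rank-deficient design column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  structure(list(y = y, X = X, ids = ids, trait = trait),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design for '", x$trait, "': ", length(x$y), " records, ",
      ncol(x$X), " fixed-effect columns (",
      paste(colnames(x$X), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Restrict a design to a subset of row indices.
subset_design <- function(dm, rows) {
  structure(list(y = dm$y[rows], X = dm$X[rows, , drop = FALSE],
                 ids = dm$ids[rows], trait = dm$trait),
            class = "design_matrix")
}
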