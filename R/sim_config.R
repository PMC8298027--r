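#' Specification of a simulated trait
#'
#' Describes one phenotype for the synthetic data generator: its narrow-sense
#' heritability, phenotypic standard deviation, fixed-effect sizes and
#' per-trait missingness. Fixed effects follow the study design: generation,
#' sex, their interaction, and an age (days of culture) covariate nested
#' within generation.
#'
#' @param name trait label (column name in the phenotype table).
#' @param h2 true narrow-sense heritability, in (0, 1).
#' @param sigma_p phenotypic standard deviation in trait units.
#' @param mean overall trait mean (intercept).
#' @param gen2_effect additive shift for generation-2 individuals.
#' @param sex_effect additive shift for males.
#' @param gen2_sex_effect generation-2 by male interaction shift.
#' @param age_slope length-2 numeric: slope of trait on age (trait units per
#'   day), one slope per generation (age is nested within generation).
#' @param missing_rate fraction of records set missing, in \[0, 1).
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(name, h2, sigma_p, mean = 0,
                       gen2_effect = 0.25 * sigma_p,
                       sex_effect = 0.10 * sigma_p,
                       gen2_sex_effect = 0.05 * sigma_p,
                       age_slope = c(0.02, 0.02) * sigma_p,
                       missing_rate = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(h2 > 0 && h2 < 1)) stop("h2 must lie in (0, 1), got ", h2)
  if (sigma_p <= 0) stop("sigma_p must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (length(age_slope) == 1L) age_slope <- rep(age_slope, 2L)
  structure(list(name = name, h2 = h2, sigma_p = sigma_p, mean = mean,
                 gen2_effect = gen2_effect, sex_effect = sex_effect,
                 gen2_sex_effect = gen2_sex_effect, age_slope = age_slope,
                 missing_rate = missing_rate),
            class = "trait_spec")
}

#' Default simulated traits
#'
#' Whole weight and soft tissue weight with the heritabilities, phenotypic
#' dispersions, means and per-trait record counts of the oyster study
#' population (h2 = 0.45 and 0.43; means 51.07 g and 9.55 g; SD 16.13 g and
#' 3.13 g; soft tissue recorded on 490 of 647 animals, hence a 0.243 missing
#' rate).
#'
#' @return list of two [trait_spec()] objects.
#' @export
default_traits <- function() {
  list(
    trait_spec("whole_weight", h2 = 0.45, sigma_p = 16.13, mean = 51.07),
    trait_spec("soft_tissue_weight", h2 = 0.43, sigma_p = 3.13, mean = 9.55,
               missing_rate = 1 - 490 / 647)
  )
}

#' Simulation configuration for a two-generation full-sib breeding design
#'
#' Encodes the mating design of the study population: generation-1 full-sib
#' families produced from unrelated founders (one sire by one dam each),
#' generation-2 families whose parents are drawn from distinct generation-1
#' families, biallelic SNP markers dropped down the pedigree, and multi-trait
#' phenotypes with a known genetic and residual correlation structure.
#'
#' @param families_gen1 number of generation-1 full-sib families.
#' @param offspring_gen1 integer range (length 2) of offspring per
#'   generation-1 family; family sizes are drawn uniformly from this range.
#' @param families_gen2 number of generation-2 full-sib families.
#' @param offspring_gen2 integer range of offspring per generation-2 family.
#' @param n_markers number of unlinked biallelic SNP markers.
#' @param founder_freq base-population allele frequency law: either a length-2
#'   numeric range for Uniform sampling, a length-`n_markers` vector of
#'   frequencies, or a function of the marker count returning one. Values must
#'   lie in (0, 1].
#' @param traits list of [trait_spec()] objects.
#' @param genetic_cor genetic correlation matrix between traits (symmetric,
#'   unit diagonal, positive semi-definite).
#' @param residual_cor residual correlation matrix; defaults to 0.30 between
#'   all trait pairs.
#' @param age_mean,age_sd days-to-harvest distribution (Normal), around the
#'   nine-month culture period.
#' @param seed integer seed; a fixed seed yields byte-identical pedigree,
#'   genotypes and phenotypes.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(families_gen1 = 57, offspring_gen1 = c(2L, 8L),
                       families_gen2 = 33, offspring_gen2 = c(12L, 15L),
                       n_markers = 13048,
                       founder_freq = c(0.05, 0.5),
                       traits = default_traits(),
                       genetic_cor = NULL,
                       residual_cor = NULL,
                       age_mean = 270, age_sd = 15,
                       seed = 1L) {
  if (families_gen1 < 1) stop("families_gen1 must be positive")
  if (families_gen2 < 0) stop("families_gen2 must be non-negative")
  if (n_markers < 1) stop("n_markers must be positive")
  check_range <- function(r, what) {
    if (length(r) != 2L || any(r < 1) || r[1] > r[2])
      stop(what, " must be a nonempty positive integer range")
    as.integer(r)
  }
  offspring_gen1 <- check_range(offspring_gen1, "offspring_gen1")
  offspring_gen2 <- check_range(offspring_gen2, "offspring_gen2")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  nt <- length(traits)
  if (nt < 1) stop("at least one trait must be specified")
  tn <- vapply(traits, function(t) t$name, character(1))
  if (anyDuplicated(tn)) stop("duplicate trait names")
  if (is.null(genetic_cor)) {
    genetic_cor <- diag(nt)
    if (nt == 2L && identical(tn, c("whole_weight", "soft_tissue_weight")))
      genetic_cor[1, 2] <- genetic_cor[2, 1] <- 0.63
  }
  if (is.null(residual_cor)) {
    residual_cor <- diag(nt)
    residual_cor[residual_cor == 0] <- 0.30
  }
  check_cor <- function(C, what) {
    C <- as.matrix(C)
    if (nrow(C) != nt || ncol(C) != nt)
      stop(what, " must be a ", nt, "x", nt, " matrix")
    if (max(abs(C - t(C))) > 1e-10) stop(what, " must be symmetric")
    if (max(abs(diag(C) - 1)) > 1e-10) stop(what, " must have unit diagonal")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(what, " is not positive semi-definite (eigenvalue ",
           format(min(ev)), ")")
    C
  }
  genetic_cor <- check_cor(genetic_cor, "genetic_cor")
  residual_cor <- check_cor(residual_cor, "residual_cor")
  structure(list(families_gen1 = as.integer(families_gen1),
                 offspring_gen1 = offspring_gen1,
                 families_gen2 = as.integer(families_gen2),
                 offspring_gen2 = offspring_gen2,
                 n_markers = as.integer(n_markers),
                 founder_freq = founder_freq,
                 traits = traits, trait_names = tn,
                 genetic_cor = genetic_cor, residual_cor = residual_cor,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$families_gen1, "gen-1 families (",
      x$offspring_gen1[1], "-", x$offspring_gen1[2], " offspring), ",
      x$families_gen2, " gen-2 families (", x$offspring_gen2[1], "-",
      x$offspring_gen2[2], " offspring), ", x$n_markers, " markers, traits: ",
      paste(x$trait_names, collapse = ", "), ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# Factor L with L %*% t(L) = C, tolerating semi-definite C (e.g. r_g = 1).
cov_factor <- function(C, what = "correlation matrix") {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop(what, " is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
}
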