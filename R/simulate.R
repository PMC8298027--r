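#' Simulate genotypes by gene dropping
#'
#' Founders are drawn from Hardy-Weinberg proportions at the configured base
#' allele frequencies; every non-founder receives one allele from each parent
#' per locus, independently across loci (markers are unlinked). Calls are
#' alternate-allele counts in \{0, 1, 2\} with no missingness.
#'
#' @param ped pedigree from [make_pedigree()] (parents must exist in the
#'   pedigree; they need not precede offspring, sorting is internal).
#' @param config a [sim_config()]; the seed used is `config$seed + 1`.
#' @return a [geno_matrix()] with one row per pedigree member (row names are
#'   the pedigree ids as character).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$n_markers
  p <- founder_frequencies(config$founder_freq, m)
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  ids <- as.character(ped$id)
  idx <- stats::setNames(seq_len(n), ids)
  s <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  d <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  a1 <- matrix(0L, n, m)  # allele inherited from sire (or founder draw)
  a2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      a1[i, ] <- stats::rbinom(m, 1L, p)
      a2[i, ] <- stats::rbinom(m, 1L, p)
    } else if (s[i] > 0L && d[i] > 0L) {
      pick1 <- stats::runif(m) < 0.5
      a1[i, ] <- ifelse(pick1, a1[s[i], ], a2[s[i], ])
      pick2 <- stats::runif(m) < 0.5
      a2[i, ] <- ifelse(pick2, a1[d[i], ], a2[d[i], ])
    } else {
      stop("individual ", ids[i], " has exactly one known parent; ",
           "gene dropping requires both or neither")
    }
  }
  calls <- a1 + a2
  dimnames(calls) <- list(ids, paste0("M", seq_len(m)))
  # restore input order
  calls <- calls[as.character(ped$id[order(ord)]), , drop = FALSE]
  geno_matrix(calls)
}

founder_frequencies <- function(spec, m) {
  p <- if (is.function(spec)) {
    spec(m)
  } else if (length(spec) == 2L && m != 2L) {
    stats::runif(m, spec[1], spec[2])
  } else if (length(spec) == m) {
    spec
  } else {
    stop("founder_freq must be a length-2 range, a length-n_markers vector, ",
         "or a function of the marker count")
  }
  if (any(p <= 0 | p > 1)) stop("founder frequencies must lie in (0, 1]")
  p
}

#' Simulate multi-trait phenotypes with known genetic architecture
#'
#' For each trait, `y = X beta + M alpha + e`: marker effects `alpha` are
#' drawn i.i.d. normal with the configured between-trait genetic correlation,
#' then scaled so that the realized variance of the true breeding values
#' `g = M alpha` (with `M` the 2p-centered call matrix) equals
#' `h2 * sigma_p^2` exactly; residuals carry the configured residual
#' correlation and variance `(1 - h2) * sigma_p^2`. Fixed effects are
#' generation, sex, their interaction, and an age covariate nested within
#' generation, with contrasts centered so the configured trait `mean` is the
#' marginal population mean (the quantity a phenotypic summary reports).
#' Phenotypes are generated for generation 1 and 2 individuals
#' (founders are unmeasured broodstock). Missingness is applied per trait.
#'
#' @param gm genotypes from [simulate_genotypes()].
#' @param ped the matching pedigree.
#' @param config a [sim_config()]; the seed used is `config$seed + 2`.
#' @return a `data.frame` (class `pheno_table`) with columns `id`,
#'   `generation`, `sex`, `age` and one column per trait, plus attributes
#'   `true_bv` (matrix of true breeding values), `true_alpha` (matrix of
#'   scaled marker effects) and `true_fixed` (fixed-effect part per record)
#'   for recovery tests.
#' @export
simulate_phenotypes <- function(gm, ped, config) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  keep <- ped$generation >= 1L
  ids <- as.character(ped$id[keep])
  gen <- ped$generation[keep]
  n <- length(ids)
  if (n < 2L) stop("fewer than two measured individuals")
  calls <- gm$calls[ids, , drop = FALSE]
  p <- colMeans(calls) / 2
  Mc <- sweep(calls, 2, 2 * p)
  m <- ncol(Mc)
  nt <- length(config$traits)

  La <- cov_factor(config$genetic_cor, "genetic correlation matrix")
  Le <- cov_factor(config$residual_cor, "residual correlation matrix")
  alpha <- matrix(stats::rnorm(m * nt), m, nt) %*% t(La)
  g_raw <- Mc %*% alpha
  e <- matrix(stats::rnorm(n * nt), n, nt) %*% t(Le)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)

  out <- data.frame(id = ids, generation = factor(gen), sex = factor(sex),
                    age = age, stringsAsFactors = FALSE)
  tbv <- matrix(NA_real_, n, nt, dimnames = list(ids, config$trait_names))
  fixed_mat <- matrix(NA_real_, n, nt,
                      dimnames = list(ids, config$trait_names))
  true_alpha <- matrix(NA_real_, m, nt,
                       dimnames = list(colnames(calls), config$trait_names))
  for (t in seq_len(nt)) {
    ts <- config$traits[[t]]
    vg <- stats::var(g_raw[, t])
    if (vg <= 0) stop("degenerate genetic values for trait ", ts$name,
                      " (no polymorphic markers?)")
    s <- sqrt(ts$h2 * ts$sigma_p^2 / vg)
    g <- g_raw[, t] * s
    true_alpha[, t] <- alpha[, t] * s
    res <- e[, t] * sqrt((1 - ts$h2) * ts$sigma_p^2)
    slope <- ts$age_slope[pmin(gen, length(ts$age_slope))]
    contrasts <- ts$gen2_effect * (gen == 2L) +
      ts$sex_effect * (sex == "M") +
      ts$gen2_sex_effect * (gen == 2L & sex == "M") +
      slope * (age - config$age_mean)
    # center the fixed-effect contrasts so `mean` is the marginal trait mean
    fixed <- ts$mean + contrasts - mean(contrasts)
    y <- fixed + g + res
    if (ts$missing_rate > 0)
      y[stats::runif(n) < ts$missing_rate] <- NA_real_
    out[[ts$name]] <- y
    tbv[, t] <- g
    fixed_mat[, t] <- fixed
  }
  attr(out, "true_bv") <- tbv
  attr(out, "true_fixed") <- fixed_mat
  attr(out, "true_alpha") <- true_alpha
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Simulate a complete dataset (pedigree, genotypes, phenotypes)
#'
#' @param config a [sim_config()].
#' @return list with elements `pedigree`, `genotypes`, `phenotypes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- make_pedigree(config)
  gm <- simulate_genotypes(ped, config)
  ph <- simulate_phenotypes(gm, ped, config)
  list(pedigree = ped, genotypes = gm, phenotypes = ph)
}
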