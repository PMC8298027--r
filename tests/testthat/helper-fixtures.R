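# Small simulation configs and independent oracles shared across tests.

tiny_config <- function(seed = 42, n_markers = 200, ...) {
  sim_config(families_gen1 = 6, offspring_gen1 = c(3, 4),
             families_gen2 = 3, offspring_gen2 = c(4, 5),
             n_markers = n_markers,
             traits = list(trait_spec("t1", h2 = 0.4, sigma_p = 2,
                                      mean = 10)),
             seed = seed, ...)
}

# One-generation design with many small families and zero fixed effects,
# convenient for variance-component oracles.
flat_trait <- function(name = "t1", h2 = 0.5, sigma_p = 1, mean = 0,
                       missing_rate = 0) {
  trait_spec(name, h2 = h2, sigma_p = sigma_p, mean = mean,
             gen2_effect = 0, sex_effect = 0, gen2_sex_effect = 0,
             age_slope = c(0, 0), missing_rate = missing_rate)
}

# Genotype matrix of measured (generation >= 1) individuals only.
measured_geno <- function(dat) {
  geno_matrix(dat$genotypes$calls[as.character(dat$phenotypes$id), ,
                                  drop = FALSE],
              imputed = dat$genotypes$imputed)
}

# Intercept-only design (drops all covariate columns from the table).
plain_design <- function(pheno, trait) {
  build_design(pheno[, c("id", trait)], trait)
}

# Recursive coefficient-of-coancestry oracle; returns 2 * kinship
# (the numerator relationship matrix), independent of the tabular method.
kinship_oracle <- function(ped) {
  ids <- as.character(ped$id)
  idx <- setNames(seq_along(ids), ids)
  s <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  d <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  n <- length(ids)
  memo <- matrix(NA_real_, n, n)
  gen_rank <- ped$generation
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == j) {
      0.5 * (1 + f(s[i], d[i]))
    } else {
      # recurse on the individual from the later generation
      if (gen_rank[i] >= gen_rank[j]) {
        0.5 * (f(s[i], j) + f(d[i], j))
      } else {
        0.5 * (f(s[j], i) + f(d[j], i))
      }
    }
    memo[i, j] <<- val
    memo[j, i] <<- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# Direct GLS oracle for the single-trait mixed model: inverts the full
# phenotypic covariance V = K sigma2_a + I sigma2_e.
gls_oracle <- function(dm, K, sigma2_a, sigma2_e) {
  Ks <- unclass(K)[dm$ids, dm$ids]
  V <- Ks * sigma2_a + diag(sigma2_e, length(dm$y))
  Vi <- solve(V)
  XtVi <- crossprod(dm$X, Vi)
  beta <- solve(XtVi %*% dm$X, XtVi %*% dm$y)
  resid <- dm$y - drop(dm$X %*% beta)
  # BLUP for every individual in K
  g <- sigma2_a * unclass(K)[, dm$ids] %*% (Vi %*% resid)
  list(beta = drop(beta), g = setNames(drop(g), rownames(K)))
}

# Balanced full-sib ANOVA estimator of heritability: h2 = 2 * t with t the
# intraclass correlation from the one-way family ANOVA.
anova_h2 <- function(y, family) {
  family <- factor(family)
  k <- length(y) / nlevels(family)
  ms <- anova(lm(y ~ family))[["Mean Sq"]]
  sb <- (ms[1] - ms[2]) / k
  2 * sb / (sb + ms[2])
}
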