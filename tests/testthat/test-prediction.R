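pred_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(families_gen1 = 15, offspring_gen1 = c(4, 4),
                        families_gen2 = 6, offspring_gen2 = c(5, 6),
                        n_markers = 400,
                        traits = list(flat_trait(h2 = 0.5, sigma_p = 2,
                                                 mean = 10)),
                        seed = 77)
      dat <- simulate_dataset(cfg)
      gm <- measured_geno(dat)
      cache <<- list(dat = dat, gm = gm, G = grm_vanraden(gm),
                     A = nrm(dat$pedigree),
                     dm = plain_design(dat$phenotypes, "t1"))
    }
    cache
  }
})

fake_vc <- function(sigma2_a, sigma2_e) {
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e), class = "vc_fit")
}

test_that("MME solution matches hand algebra on two records of one animal", {
  # one individual, K = [1], two records of the mean-only model
  y <- c(3, 5)
  dm <- structure(list(y = y, X = matrix(1, 2, 1,
                                         dimnames = list(NULL, "mu")),
                       ids = c("i1", "i1"), trait = "y"),
                  class = "design_matrix")
  K <- relmat(matrix(1, 1, 1, dimnames = list("i1", "i1")), kind = "A")
  vc <- fake_vc(2, 1)  # lambda = 0.5
  fit <- solve_mme(dm, K, vc)
  # closed form: MME [[2, 2], [2, 2 + lambda]] [b, g] = [sum y, sum y]
  lambda <- 0.5
  sol <- solve(matrix(c(2, 2, 2, 2 + lambda), 2, 2), c(sum(y), sum(y)))
  expect_equal(unname(fit$beta), sol[1], tolerance = 1e-12)
  expect_equal(unname(fit$g), sol[2], tolerance = 1e-12)
})

test_that("complete shrinkage: genetic values vanish as lambda grows", {
  fx <- pred_fixture()
  fit <- suppressMessages(solve_mme(fx$dm, fx$G, fake_vc(1e-9, 1)))
  expect_lt(max(abs(fit$g)), 1e-6 * sd(fx$dm$y))
})

test_that("MME equals the direct GLS/joint-covariance oracle at small n", {
  fx <- pred_fixture()
  rows <- 1:28
  dm_s <- structure(list(y = fx$dm$y[rows],
                         X = fx$dm$X[rows, , drop = FALSE],
                         ids = fx$dm$ids[rows], trait = "t1"),
                    class = "design_matrix")
  for (K in list(fx$G, fx$A)) {
    Kb <- relmat(bend_psd(unclass(K)), kind = attr(K, "kind"))
    vc <- fake_vc(1.5, 0.8)
    fit <- solve_mme(dm_s, Kb, vc)
    ora <- gls_oracle(dm_s, Kb, 1.5, 0.8)
    expect_equal(unname(fit$beta), unname(ora$beta), tolerance = 1e-8)
    expect_equal(fit$g, ora$g, tolerance = 1e-8)
  }
})

test_that("GBLUP with G set to A reproduces pedigree BLUP", {
  fx <- pred_fixture()
  vc <- fake_vc(1.2, 0.9)
  fit_a <- solve_mme(fx$dm, fx$A, vc)
  A_as_G <- relmat(unclass(fx$A), kind = "G_vanraden",
                   scaling = attr(fx$G, "scaling"))
  fit_g <- solve_mme(fx$dm, A_as_G, vc)
  expect_equal(fit_g$beta, fit_a$beta, tolerance = 1e-8)
  expect_equal(fit_g$g, fit_a$g, tolerance = 1e-8)
})

test_that("allele substitution effects reconstruct the genetic values", {
  fx <- pred_fixture()
  vc <- reml_univariate(fx$dm, fx$G)
  fit <- suppressMessages(solve_mme(fx$dm, fx$G, vc))
  alpha <- backsolve_ase(fit, fx$gm)
  expect_equal(length(alpha), ncol(fx$gm$calls))
  expect_lt(attr(alpha, "recon_error"), 1e-6)

  # zero genetic values give zero effects
  fit0 <- fit
  fit0$g[] <- 0
  alpha0 <- backsolve_ase(fit0, fx$gm)
  expect_equal(max(abs(alpha0)), 0)

  # pedigree kinship cannot be back-solved
  fit_a <- solve_mme(fx$dm, fx$A, fake_vc(1, 1))
  expect_error(backsolve_ase(fit_a, fx$gm), "genomic")
})

test_that("single-marker effect equals the genotype contrast slope", {
  # two individuals differing at one marker: alpha = delta g / delta M
  gm <- geno_matrix(matrix(c(0, 2), 2, 1,
                           dimnames = list(c("i1", "i2"), "m1")))
  ghat <- c(i1 = -0.4, i2 = 0.4)
  fit <- structure(list(g = ghat, kind = "G_vanraden"), class = "blup_fit")
  alpha <- backsolve_ase(fit, gm)
  expect_equal(as.numeric(alpha), unname(diff(ghat)) / 2, tolerance = 1e-10)
})

test_that("phenotype prediction composes fixed and marker effects", {
  fx <- pred_fixture()
  vc <- reml_univariate(fx$dm, fx$G)
  fit <- suppressMessages(solve_mme(fx$dm, fx$G, vc))
  alpha <- backsolve_ase(fit, fx$gm)
  M_new <- fx$gm$calls[fx$dm$ids, , drop = FALSE]
  yhat_ase <- predict_phenotypes(fx$dm$X, fit$beta, M_new, alpha)
  yhat_mme <- drop(fx$dm$X %*% fit$beta) + fit$g[fx$dm$ids]
  expect_equal(yhat_ase, unname(yhat_mme), tolerance = 1e-6,
               ignore_attr = TRUE)

  # alpha = 0 leaves only the fixed part
  expect_equal(predict_phenotypes(fx$dm$X, fit$beta),
               drop(fx$dm$X %*% fit$beta))
  expect_error(predict_phenotypes(fx$dm$X, fit$beta,
                                  M_new[, 1:3, drop = FALSE], alpha),
               "marker mismatch")
})

test_that("held-out predictions via ASE equal MME genetic values", {
  fx <- pred_fixture()
  n <- length(fx$dm$y)
  test_rows <- seq(1, n, by = 5)
  train <- setdiff(seq_len(n), test_rows)
  dtrain <- structure(list(y = fx$dm$y[train],
                           X = fx$dm$X[train, , drop = FALSE],
                           ids = fx$dm$ids[train], trait = "t1"),
                      class = "design_matrix")
  vc <- reml_univariate(dtrain, fx$G)
  fit <- suppressMessages(solve_mme(dtrain, fx$G, vc))
  alpha <- backsolve_ase(fit, fx$gm)
  val_ids <- fx$dm$ids[test_rows]
  yhat_mme <- drop(fx$dm$X[test_rows, , drop = FALSE] %*% fit$beta) +
    fit$g[val_ids]
  yhat_ase <- predict_phenotypes(fx$dm$X[test_rows, , drop = FALSE],
                                 fit$beta,
                                 fx$gm$calls[val_ids, , drop = FALSE],
                                 alpha)
  expect_equal(yhat_ase, unname(yhat_mme), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("fold assignment partitions near-equally and reproducibly", {
  f <- make_folds(647, 5, seed = 1)
  expect_equal(as.vector(sort(table(f), decreasing = TRUE)),
               c(130, 130, 129, 129, 129))
  expect_identical(make_folds(647, 5, seed = 1), f)
  expect_false(identical(make_folds(647, 5, seed = 2), f))
})

test_that("cross-validation is reproducible and summarizes correctly", {
  fx <- pred_fixture()
  cv <- suppressMessages(suppressWarnings(
    cross_validate(fx$dat$phenotypes, "t1", gm = fx$gm, method = "gblup",
                   k = 4, replicates = 2, seed = 5)))
  # folds partition the samples within each replicate
  for (r in 1:2) {
    rec <- cv$records[cv$records$replicate == r, ]
    expect_setequal(rec$id, fx$dm$ids)
  }
  # summary R2 equals the regression recomputed from the records
  rec1 <- cv$records[cv$records$replicate == 1, ]
  expect_equal(cv$r2_by_replicate[1],
               summary(lm(observed ~ predicted, rec1))$r.squared)
  expect_true(all(cv$r2_by_replicate >= 0 & cv$r2_by_replicate <= 1))
  expect_equal(cv$r2_mean, mean(cv$r2_by_replicate))
  expect_equal(cv$r2_best, max(cv$r2_by_replicate))

  cv2 <- suppressMessages(suppressWarnings(
    cross_validate(fx$dat$phenotypes, "t1", gm = fx$gm, method = "gblup",
                   k = 4, replicates = 2, seed = 5)))
  expect_identical(cv$records, cv2$records)

  # a perfect predictor has R2 exactly 1
  perfect <- data.frame(observed = rnorm(30))
  perfect$predicted <- perfect$observed
  r2_perfect <- suppressWarnings(
    summary(lm(observed ~ predicted, perfect))$r.squared)
  expect_equal(r2_perfect, 1)

  expect_error(cross_validate(fx$dat$phenotypes, "t1", gm = fx$gm,
                              k = 60, replicates = 1),
               "smaller k")
})

test_that("family-stratified folds keep full-sib families together", {
  fx <- pred_fixture()
  ped <- fx$dat$pedigree
  fam <- setNames(paste(ped$sire, ped$dam),
                  as.character(ped$id))[as.character(fx$dat$phenotypes$id)]
  cv <- suppressMessages(suppressWarnings(
    cross_validate(fx$dat$phenotypes, "t1", gm = fx$gm, method = "gblup",
                   k = 4, replicates = 1, seed = 8, stratify_by = fam)))
  # every family appears in exactly one fold
  fold_of <- tapply(cv$records$fold, fam[cv$records$id],
                    function(x) length(unique(x)))
  expect_true(all(fold_of == 1))
  expect_setequal(cv$records$id, fx$dm$ids)
})

test_that("strict exclusion predicts held-out animals through markers only", {
  fx <- pred_fixture()
  cv <- suppressMessages(suppressWarnings(
    cross_validate(fx$dat$phenotypes, "t1", gm = fx$gm, method = "gblup",
                   k = 4, replicates = 1, seed = 8,
                   strict_exclusion = TRUE)))
  expect_setequal(cv$records$id, fx$dm$ids)
  expect_true(all(is.finite(cv$records$predicted)))
  expect_true(cv$r2_mean >= 0 && cv$r2_mean <= 1)
  expect_error(
    cross_validate(fx$dat$phenotypes, "t1", pedigree = fx$dat$pedigree,
                   method = "ablup", strict_exclusion = TRUE),
    "gblup")
})
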