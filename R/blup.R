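#' Solve Henderson's mixed-model equations
#'
#' Computes BLUE fixed effects and BLUP genetic values for
#' `y = X beta + Z g + e`, `g ~ N(0, K sigma2_a)`, `e ~ N(0, I sigma2_e)`,
#' with shrinkage `lambda = sigma2_e / sigma2_a` on the random block.
#' Every individual in `K` receives a genetic value, including individuals
#' without phenotypes (their records are simply absent from `y`), which is
#' how held-out animals are predicted in cross-validation.
#'
#' @param dm a [build_design()] object (the phenotyped records).
#' @param K a [relmat] covering at least the phenotyped ids; bent via
#'   [bend_psd()] before inversion if needed.
#' @param vc a `vc_fit` (or list with `sigma2_a`, `sigma2_e`).
#' @return an object of class `blup_fit` with `beta` (named fixed-effect
#'   solutions), `g` (named genetic values for all ids in `K`), `lambda`,
#'   `kind` and the variance components used.
#' @export
solve_mme <- function(dm, K, vc) {
  stopifnot(inherits(dm, "design_matrix"))
  if (vc$sigma2_a <= 0 || vc$sigma2_e <= 0)
    stop("solve_mme requires positive variance components")
  ids_all <- rownames(K)
  miss <- setdiff(dm$ids, ids_all)
  if (length(miss))
    stop("phenotyped ids missing from K: ",
         paste(utils::head(miss, 5), collapse = ", "))
  lambda <- vc$sigma2_e / vc$sigma2_a
  Kb <- bend_psd(unclass(K))
  Kinv <- tryCatch(solve(Kb), error = function(e)
    stop("relationship matrix singular even after bending"))
  n_all <- nrow(Kb)
  ridx <- match(dm$ids, ids_all)
  Z <- matrix(0, length(dm$y), n_all)
  Z[cbind(seq_along(ridx), ridx)] <- 1
  X <- dm$X
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  RHS <- c(crossprod(X, dm$y), crossprod(Z, dm$y))
  sol <- solve(LHS, RHS)
  p <- ncol(X)
  structure(list(beta = stats::setNames(sol[seq_len(p)], colnames(X)),
                 g = stats::setNames(sol[-seq_len(p)], ids_all),
                 lambda = lambda, kind = attr(K, "kind"), vc = vc,
                 trait = dm$trait, ids_pheno = dm$ids),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("Mixed-model solution (", x$kind, "), trait '", x$trait, "': ",
      length(x$beta), " fixed effects, ", length(x$g),
      " genetic values, lambda = ", signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$beta

#' Genetic values (BLUP) of a mixed-model solution
#' @param fit a `blup_fit`.
#' @return named numeric vector of genetic values.
#' @export
genetic_values <- function(fit) fit$g

#' Back-solve per-marker allele substitution effects from GBLUP
#'
#' Computes `alpha = M' G^- g / sum(2pq)` with `M` the 2p-centered call
#' matrix and `G^-` the eigenvalue pseudo-inverse of `G = M M' / sum(2pq)`,
#' so that `M alpha` reconstructs the genetic values exactly whenever the
#' genetic values lie in the column space of `M` (always true for BLUP
#' solutions, which are shrunken through `G`). The pseudo-inverse handles the
#' rank deficiency that sample-frequency centering always induces; any
#' residual reconstruction error is reported.
#'
#' @param fit a `blup_fit` from a genomic (VanRaden) kinship.
#' @param gm the imputed [geno_matrix()] used to build `G` (same markers).
#' @return named numeric vector of allele substitution effects, with the
#'   relative reconstruction error in attribute `recon_error`.
#' @export
backsolve_ase <- function(fit, gm) {
  stopifnot(inherits(fit, "blup_fit"), inherits(gm, "geno_matrix"))
  if (!identical(fit$kind, "G_vanraden"))
    stop("allele substitution effects require a genomic (VanRaden) kinship; ",
         "got ", fit$kind)
  ids <- intersect(names(fit$g), sample_ids(gm))
  if (length(ids) == 0) stop("no overlap between fit and genotype samples")
  calls <- gm$calls[ids, , drop = FALSE]
  p <- colMeans(calls) / 2
  s2pq <- sum(2 * p * (1 - p))
  M <- sweep(calls, 2, 2 * p)
  G <- tcrossprod(M) / s2pq
  ghat <- fit$g[ids]
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  Ginv_g <- e$vectors[, keep, drop = FALSE] %*%
    (crossprod(e$vectors[, keep, drop = FALSE], ghat) / e$values[keep])
  alpha <- drop(crossprod(M, Ginv_g)) / s2pq
  recon <- drop(M %*% alpha)
  err <- sqrt(sum((recon - ghat)^2)) / max(sqrt(sum(ghat^2)), 1e-300)
  if (err > 1e-6)
    message("backsolve_ase: relative reconstruction error ",
            format(err, digits = 3))
  structure(stats::setNames(alpha, marker_ids(gm)), recon_error = err,
            freq = p)
}

#' Predict phenotypes from fixed effects and allele substitution effects
#'
#' `y_hat = X_new beta + M_new alpha`, where `M_new` is centered with the
#' TRAINING allele frequencies (`freq`), the frequencies under which `alpha`
#' was back-solved.
#'
#' @param X_new fixed-effects design matrix of the individuals to predict.
#' @param beta fixed-effect solutions (same columns as `X_new`).
#' @param M_new raw calls of the new individuals (same markers as `alpha`),
#'   or `NULL` to predict from fixed effects only.
#' @param alpha allele substitution effects from [backsolve_ase()].
#' @param freq training allele frequencies used for centering; defaults to
#'   the `freq` attribute of `alpha`.
#' @return numeric vector of predicted phenotypes.
#' @export
predict_phenotypes <- function(X_new, beta, M_new = NULL, alpha = NULL,
                               freq = attr(alpha, "freq")) {
  yhat <- drop(X_new %*% beta)
  if (!is.null(alpha)) {
    if (is.null(M_new)) stop("alpha supplied without M_new")
    if (ncol(M_new) != length(alpha))
      stop("marker mismatch: M_new has ", ncol(M_new), " markers, alpha has ",
           length(alpha))
    if (is.null(freq)) stop("training allele frequencies required")
    Mc <- sweep(M_new, 2, 2 * freq)
    yhat <- yhat + drop(Mc %*% alpha)
  }
  yhat
}

#' Random near-equal fold assignment
#'
#' Partitions `n` samples into `k` folds whose sizes differ by at most one
#' (e.g. 647 samples in 5 folds give sizes 130, 130, 129, 129, 129).
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed optional integer seed.
#' @return integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Replicated k-fold cross-validated predictive ability
#'
#' For each replicate, phenotyped samples are randomly partitioned into `k`
#' near-equal folds. For each fold, variance components are re-estimated on
#' the training records only, the mixed-model equations are solved with the
#' held-out phenotypes removed but the held-out individuals retained in the
#' relationship matrix, and the held-out phenotypes are predicted as
#' `X beta + g_hat`. Predictive ability is the coefficient of determination
#' R2 of the regression of observed on predicted phenotypes, pooled within a
#' replicate and averaged across replicates (the largest single-replicate R2
#' is also reported).
#'
#' @param pheno phenotype `data.frame` (see [build_design()]).
#' @param trait trait column name.
#' @param gm imputed [geno_matrix()] (required for `method = "gblup"`).
#' @param pedigree pedigree `data.frame` (required for `method = "ablup"`).
#' @param method `"gblup"` (genomic kinship) or `"ablup"` (pedigree
#'   numerator kinship).
#' @param k number of folds.
#' @param replicates number of replicates.
#' @param seed integer seed for the fold assignments (replicate `r` uses
#'   `seed + r`).
#' @param grm `"vanraden"` or `"gcta"` for the genomic kinship.
#' @param options [reml_options()] for the per-fold REML fits.
#' @param stratify_by optional grouping vector (named by sample id, or a
#'   column name of `pheno` such as a family label): whole groups are
#'   assigned to folds, so no group straddles training and validation.
#'   Family structure inflates the accuracy of sample-random folds; family
#'   stratification removes that optimism.
#' @param strict_exclusion if `TRUE` (GBLUP only), held-out individuals are
#'   removed from the relationship matrix during training and predicted
#'   through back-solved allele substitution effects (`X beta + M alpha` with
#'   `M` centered at the training allele frequencies). The default keeps
#'   held-out genotypes in `G` with their phenotypes masked.
#' @return an object of class `cv_result`: a per-record table (`replicate`,
#'   `fold`, `id`, `observed`, `predicted`) and a summary with mean and
#'   best-replicate R2 and Pearson correlation.
#' @export
cross_validate <- function(pheno, trait, gm = NULL, pedigree = NULL,
                           method = c("gblup", "ablup"), k = 5L,
                           replicates = 5L, seed = 1L,
                           grm = c("vanraden", "gcta"),
                           options = reml_options(),
                           stratify_by = NULL, strict_exclusion = FALSE) {
  method <- match.arg(method)
  grm <- match.arg(grm)
  if (strict_exclusion && method != "gblup")
    stop("strict exclusion requires marker-based prediction (gblup)")
  K <- if (method == "gblup") {
    if (is.null(gm)) stop("gblup requires a genotype matrix")
    if (grm == "vanraden") grm_vanraden(gm) else grm_gcta(gm)
  } else {
    if (is.null(pedigree)) stop("ablup requires a pedigree")
    nrm(pedigree)
  }
  dm <- build_design(pheno, trait)
  n <- length(dm$y)
  if (floor(n / k) < 3)
    stop("fold(s) with fewer than 3 samples: use a smaller k")
  if (!is.null(stratify_by)) {
    if (is.character(stratify_by) && length(stratify_by) == 1L)
      stratify_by <- stats::setNames(pheno[[stratify_by]],
                                     as.character(pheno$id))
    group <- if (!is.null(names(stratify_by))) {
      stratify_by[dm$ids]
    } else {
      stop("stratify_by must be named by sample id or name a pheno column")
    }
    if (anyNA(group)) stop("stratify_by misses some phenotyped samples")
  }
  rows <- vector("list", replicates * k)
  r2 <- r_pearson <- numeric(replicates)
  idx <- 1L
  for (r in seq_len(replicates)) {
    if (is.null(stratify_by)) {
      fold <- make_folds(n, k, seed = seed + r)
    } else {
      set.seed(seed + r)
      grp <- unique(group)
      gfold <- stats::setNames(sample(rep(seq_len(k), length.out =
                                          length(grp))), grp)
      fold <- unname(gfold[as.character(group)])
    }
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(test) == 0L) next
      dtrain <- subset_design(dm, train)
      if (strict_exclusion) {
        train_ids <- unique(dm$ids[train])
        gm_train <- geno_matrix(gm$calls[train_ids, , drop = FALSE],
                                imputed = gm$imputed)
        K_train <- if (grm == "vanraden") grm_vanraden(gm_train)
                   else grm_gcta(gm_train)
        vc <- suppressWarnings(reml_univariate(dtrain, K_train, options))
        fit <- solve_mme(dtrain, K_train, vc)
        alpha <- backsolve_ase(fit, gm_train)
        yhat <- predict_phenotypes(dm$X[test, , drop = FALSE], fit$beta,
                                   gm$calls[dm$ids[test], , drop = FALSE],
                                   alpha)
      } else {
        vc <- suppressWarnings(reml_univariate(dtrain, K, options))
        fit <- solve_mme(dtrain, K, vc)
        yhat <- drop(dm$X[test, , drop = FALSE] %*% fit$beta) +
          fit$g[dm$ids[test]]
      }
      rows[[idx]] <- data.frame(replicate = r, fold = f, id = dm$ids[test],
                                observed = dm$y[test],
                                predicted = unname(yhat))
      idx <- idx + 1L
    }
    done <- rows[!vapply(rows, is.null, logical(1))]
    rep_rows <- do.call(rbind, done)
    rep_rows <- rep_rows[rep_rows$replicate == r, ]
    fit_lm <- stats::lm(observed ~ predicted, data = rep_rows)
    r2[r] <- summary(fit_lm)$r.squared
    r_pearson[r] <- stats::cor(rep_rows$observed, rep_rows$predicted)
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(records = records, trait = trait, method = method,
                 kind = attr(K, "kind"), k = k, replicates = replicates,
                 seed = seed, r2_by_replicate = r2,
                 r_by_replicate = r_pearson,
                 r2_mean = mean(r2), r2_best = max(r2),
                 r_mean = mean(r_pearson)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV (%d replicates), trait '%s', %s:\n  mean R2 = %.3f (best replicate %.3f), mean r = %.3f\n",
    x$k, x$replicates, x$trait, x$method, x$r2_mean, x$r2_best, x$r_mean))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  plot(x$records$predicted, x$records$observed,
       xlab = "Predicted phenotype", ylab = "Observed phenotype",
       main = sprintf("%s, %s: mean R2 = %.2f", x$trait, x$method,
                      x$r2_mean), ...)
  graphics::abline(stats::lm(observed ~ predicted, data = x$records),
                   col = 2)
  invisible(x)
}
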