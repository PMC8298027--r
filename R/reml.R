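#' Options for the AI-REML iteration
#'
#' @param max_iter maximum number of iterations.
#' @param tol_logl convergence threshold on the change in restricted
#'   log-likelihood.
#' @param tol_par convergence threshold on the relative parameter change.
#' @param em_only if `TRUE`, use only EM steps (each EM step cannot decrease
#'   the restricted likelihood); mainly for diagnostics.
#' @param verbose print the likelihood trace.
#' @return list of options.
#' @export
reml_options <- function(max_iter = 100L, tol_logl = 1e-6, tol_par = 1e-5,
                         em_only = FALSE, verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol_logl = tol_logl,
       tol_par = tol_par, em_only = em_only, verbose = verbose)
}

# Generic AI-REML driver.
#
# evalfun(theta) must return NULL when theta is outside the parameter space,
# otherwise list(logL, grad, AI, quad, tr) where grad = -0.5*(tr - quad).
# EM fallback: theta_k <- theta_k + theta_k^2 * (quad_k - tr_k) / n_rec,
# which never decreases the restricted likelihood. `project` repairs
# out-of-space proposals (floors, positive-definiteness of covariance
# blocks); `free` marks parameters that are updated (others stay fixed).
ai_reml_core <- function(theta, evalfun, project, lower, n_rec, opts,
                         free = rep(TRUE, length(theta))) {
  ev <- evalfun(theta)
  if (is.null(ev)) {
    theta <- project(theta)
    ev <- evalfun(theta)
    if (is.null(ev)) stop("starting values outside the parameter space")
  }
  trace <- ev$logL
  converged <- FALSE
  used_em <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    prop <- NULL
    ev_new <- NULL
    if (!opts$em_only) {
      step <- tryCatch(solve(ev$AI[free, free, drop = FALSE],
                             ev$grad[free]),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        half <- 1
        for (try in 1:6) {
          cand <- theta
          cand[free] <- theta[free] + half * step
          cand <- project(cand)
          cand_ev <- evalfun(cand)
          if (!is.null(cand_ev) && is.finite(cand_ev$logL) &&
              cand_ev$logL >= ev$logL - 1e-4 * (abs(ev$logL) + 1)) {
            prop <- cand; ev_new <- cand_ev
            break
          }
          half <- half / 2
        }
      }
    }
    if (is.null(prop)) {
      # EM fallback step (monotone in the restricted likelihood)
      used_em <- TRUE
      cand <- theta
      cand[free] <- theta[free] +
        theta[free]^2 * (ev$quad[free] - ev$tr[free]) / n_rec
      cand <- project(cand)
      ev_new <- evalfun(cand)
      if (is.null(ev_new)) break
      prop <- cand
    }
    d_logl <- ev_new$logL - ev$logL
    d_par <- max(abs(prop - theta) / pmax(abs(theta), 1e-12))
    if (opts$verbose)
      cat(sprintf("iter %3d logL %.8f dlogL %.2e dpar %.2e\n",
                  it, ev_new$logL, d_logl, d_par))
    theta <- prop
    ev <- ev_new
    trace <- c(trace, ev$logL)
    if (abs(d_logl) < opts$tol_logl && d_par < opts$tol_par) {
      converged <- TRUE
      break
    }
  }
  boundary <- any(theta[free] <= lower[free] * (1 + 1e-6) + 1e-300)
  list(theta = theta, logL = ev$logL, trace = trace, iterations = it,
       converged = converged, used_em = used_em, boundary = boundary,
       AI = ev$AI, ev = ev)
}

#' Univariate AI-REML for the animal model
#'
#' Fits `y = X beta + g + e` with `g ~ N(0, K sigma2_a)` and
#' `e ~ N(0, I sigma2_e)` by average-information REML, via the eigenvalue
#' rotation of the (subsetted) relationship matrix: after rotating by the
#' eigenvectors of `K`, the covariance is diagonal and every iteration is
#' linear in the record count. EM steps are substituted whenever an AI update
#' leaves the parameter space or fails to improve the restricted likelihood.
#' Variances are floored at `1e-6 * var(y)`; boundary hits are flagged.
#'
#' @param dm a [build_design()] object; its `ids` must appear in
#'   `rownames(K)`.
#' @param K a [relmat] (genomic or pedigree).
#' @param options a [reml_options()] list.
#' @return an object of class `vc_fit`: variance components `sigma2_a`,
#'   `sigma2_e`, `sigma2_p`, heritability `h2` with delta-method `se_h2`,
#'   component standard errors from the inverse average-information matrix,
#'   log-likelihood trace, convergence state and flags.
#' @export
reml_univariate <- function(dm, K, options = reml_options()) {
  stopifnot(inherits(dm, "design_matrix"))
  miss <- setdiff(dm$ids, rownames(K))
  if (length(miss))
    stop("design rows missing from the relationship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- length(dm$y)
  if (n <= ncol(dm$X) + 2) stop("too few records for REML")
  Ks <- unclass(K)[dm$ids, dm$ids]
  e <- eigen(Ks, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ystar <- drop(crossprod(U, dm$y))
  Xstar <- crossprod(U, dm$X)
  non_identifiable <- diff(range(d)) < 1e-8
  if (non_identifiable)
    warning("relationship matrix is (a multiple of) the identity: ",
            "genetic and residual variances are not separately identifiable")

  vy <- stats::var(dm$y)
  floor_v <- 1e-6 * vy
  evalfun <- function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    w <- 1 / v
    A <- crossprod(Xstar, Xstar * w)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    Ainv <- chol2inv(cA)
    beta <- Ainv %*% crossprod(Xstar, ystar * w)
    r <- ystar - drop(Xstar %*% beta)
    Py <- w * r
    logL <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cA))) + sum(r * Py))
    Papply <- function(x) {
      wx <- w * x
      wx - w * drop(Xstar %*% (Ainv %*% crossprod(Xstar, wx)))
    }
    tr_v <- c(sum(w * d), sum(w))
    T1 <- crossprod(Xstar, Xstar * (w^2 * d))
    T2 <- crossprod(Xstar, Xstar * w^2)
    tr <- c(tr_v[1] - sum(Ainv * T1), tr_v[2] - sum(Ainv * T2))
    quad <- c(sum(d * Py^2), sum(Py^2))
    u1 <- d * Py
    Pu1 <- Papply(u1)
    Pu2 <- Papply(Py)
    AI <- 0.5 * matrix(c(sum(u1 * Pu1), sum(u1 * Pu2),
                         sum(u1 * Pu2), sum(Py * Pu2)), 2, 2)
    list(logL = logL, grad = -0.5 * (tr - quad), AI = AI,
         quad = quad, tr = tr)
  }
  project <- function(theta) pmax(theta, floor_v)
  theta0 <- c(vy / 2, vy / 2)
  fit <- ai_reml_core(theta0, evalfun, project, rep(floor_v, 2), n, options)

  sa <- fit$theta[1]; se_ <- fit$theta[2]
  AIinv <- tryCatch(solve(fit$AI), error = function(e)
    matrix(NA_real_, 2, 2))
  sp <- sa + se_
  gh <- c(se_, -sa) / sp^2
  se_h2 <- sqrt(max(drop(t(gh) %*% AIinv %*% gh), 0))
  structure(list(
    bivariate = FALSE, trait = dm$trait, kind = attr(K, "kind"),
    n = n, sigma2_a = sa, sigma2_e = se_, sigma2_p = sp,
    h2 = sa / sp, se_h2 = se_h2,
    se_components = sqrt(pmax(diag(AIinv), 0)),
    ai_inverse = AIinv, logL = fit$logL, logL_trace = fit$trace,
    iterations = fit$iterations, converged = fit$converged,
    boundary = fit$boundary, non_identifiable = non_identifiable),
    class = "vc_fit")
}

#' Heritability and its standard error
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`; the standard error comes from the
#' delta method applied to the inverse average-information matrix.
#'
#' @param vc a `vc_fit` from [reml_univariate()] or [reml_bivariate()].
#' @return for a univariate fit, `c(h2, se)`; for a bivariate fit, a 2-row
#'   matrix with one row per trait.
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "vc_fit"))
  if (!vc$bivariate) {
    if (vc$sigma2_p <= 0) stop("phenotypic variance is zero")
    return(c(h2 = vc$h2, se = vc$se_h2))
  }
  out <- cbind(h2 = vc$h2, se = vc$se_h2)
  rownames(out) <- vc$trait
  out
}

#' @export
print.vc_fit <- function(x, ...) {
  if (!x$bivariate) {
    cat("Animal model REML (", x$kind, " kinship), trait '", x$trait,
        "', n = ", x$n, "\n", sep = "")
    cat(sprintf("  sigma2_a = %.4g  sigma2_e = %.4g  h2 = %.3f (SE %.3f)\n",
                x$sigma2_a, x$sigma2_e, x$h2, x$se_h2))
  } else {
    cat("Bivariate animal model REML (", x$kind, " kinship), traits '",
        x$trait[1], "' / '", x$trait[2], "'\n", sep = "")
    cat(sprintf("  h2 = %.3f (SE %.3f) / %.3f (SE %.3f)\n",
                x$h2[1], x$se_h2[1], x$h2[2], x$se_h2[2]))
    cat(sprintf("  r_g = %.3f (SE %.3f)   r_e = %.3f\n",
                x$r_g, x$se_rg, x$r_e))
  }
  cat(sprintf("  logL = %.4f after %d iterations (%s%s%s)\n", x$logL,
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$boundary) ", boundary" else "",
              if (isTRUE(x$non_identifiable)) ", non-identifiable" else ""))
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Bivariate AI-REML for the two-trait animal model
#'
#' Fits genetic covariance `Sigma_a (x) K` and residual covariance
#' `Sigma_e (x) I`, where the residual covariance between traits applies only
#' to individuals recorded for both (records on a single trait contribute
#' only their own-trait residual; standard missing-at-random treatment).
#' When both traits are observed on exactly the same samples, an eigenvalue
#' rotation of `K` makes each iteration linear in the record count; otherwise
#' the full dense covariance is used. A `Sigma_a` (or `Sigma_e`) update that
#' is not positive definite is projected back to the PD cone.
#'
#' @param dm1,dm2 [build_design()] objects for the two traits (sample sets
#'   may overlap without being equal).
#' @param K a [relmat].
#' @param options a [reml_options()] list.
#' @param force_dense use the dense-covariance path even for complete
#'   records (the two paths compute the same likelihood; mainly for
#'   verification).
#' @return a `vc_fit` with per-trait `sigma2_a`, `sigma2_e`, `h2`, `se_h2`,
#'   the genetic covariance `sigma_a12`, `r_g` with delta-method `se_rg`, the
#'   residual correlation `r_e`, and convergence state.
#' @export
reml_bivariate <- function(dm1, dm2, K, options = reml_options(),
                           force_dense = FALSE) {
  stopifnot(inherits(dm1, "design_matrix"), inherits(dm2, "design_matrix"))
  for (dm in list(dm1, dm2)) {
    miss <- setdiff(dm$ids, rownames(K))
    if (length(miss))
      stop("design rows missing from the relationship matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  n1 <- length(dm1$y); n2 <- length(dm2$y)
  n_rec <- n1 + n2
  n_both <- length(intersect(dm1$ids, dm2$ids))
  vy1 <- stats::var(dm1$y); vy2 <- stats::var(dm2$y)
  floors <- c(1e-6 * vy1, -Inf, 1e-6 * vy2, 1e-6 * vy1, -Inf, 1e-6 * vy2)
  free <- rep(TRUE, 6)
  if (n_both < 3) free[5] <- FALSE  # residual covariance unidentifiable

  project <- function(theta) {
    theta[c(1, 3, 4, 6)] <- pmax(theta[c(1, 3, 4, 6)],
                                 floors[c(1, 3, 4, 6)])
    fix_cov <- function(v11, v12, v22) {
      b <- 0.999 * sqrt(v11 * v22)
      if (abs(v12) > b) v12 <- sign(v12) * b
      v12
    }
    theta[2] <- fix_cov(theta[1], theta[2], theta[3])
    theta[5] <- fix_cov(theta[4], theta[5], theta[6])
    theta
  }

  same_set <- setequal(dm1$ids, dm2$ids) && n1 == n2 && !force_dense
  if (same_set) {
    ord <- match(dm1$ids, dm2$ids)
    dm2 <- subset_design(dm2, ord)
    eng <- biv_eval_rotated(dm1, dm2, K)
  } else {
    eng <- biv_eval_dense(dm1, dm2, K)
  }

  # start values: half the marginal variances, mild positive covariance share
  r12 <- if (n_both >= 3) {
    i1 <- match(intersect(dm1$ids, dm2$ids), dm1$ids)
    i2 <- match(intersect(dm1$ids, dm2$ids), dm2$ids)
    stats::cov(dm1$y[i1], dm2$y[i2])
  } else 0
  theta0 <- project(c(vy1 / 2, r12 / 4, vy2 / 2, vy1 / 2, r12 / 4, vy2 / 2))
  fit <- ai_reml_core(theta0, eng, project, floors, n_rec, options,
                      free = free)
  th <- fit$theta
  AIinv <- tryCatch(solve(fit$AI[free, free, drop = FALSE]),
                    error = function(e)
                      matrix(NA_real_, sum(free), sum(free)))
  AIfull <- matrix(0, 6, 6)
  AIfull[free, free] <- AIinv
  sa <- c(th[1], th[3]); se_ <- c(th[4], th[6])
  sp <- sa + se_
  h2 <- sa / sp
  se_h2 <- vapply(1:2, function(t) {
    ia <- if (t == 1) 1 else 3
    ie <- if (t == 1) 4 else 6
    g <- numeric(6)
    g[ia] <- se_[t] / sp[t]^2
    g[ie] <- -sa[t] / sp[t]^2
    sqrt(max(drop(t(g) %*% AIfull %*% g), 0))
  }, numeric(1))
  rg <- th[2] / sqrt(th[1] * th[3])
  rg <- max(min(rg, 1), -1)
  g <- numeric(6)
  g[1] <- -rg / (2 * th[1])
  g[2] <- 1 / sqrt(th[1] * th[3])
  g[3] <- -rg / (2 * th[3])
  se_rg <- sqrt(max(drop(t(g) %*% AIfull %*% g), 0))
  re <- if (free[5]) th[5] / sqrt(th[4] * th[6]) else NA_real_
  structure(list(
    bivariate = TRUE, trait = c(dm1$trait, dm2$trait),
    kind = attr(K, "kind"), n = c(n1, n2), n_both = n_both,
    sigma2_a = sa, sigma2_e = se_, sigma2_p = sp,
    sigma_a12 = th[2], sigma_e12 = if (free[5]) th[5] else 0,
    h2 = h2, se_h2 = se_h2, r_g = rg, se_rg = se_rg, r_e = re,
    theta = th, ai_inverse = AIfull,
    logL = fit$logL, logL_trace = fit$trace, iterations = fit$iterations,
    converged = fit$converged, boundary = fit$boundary),
    class = "vc_fit")
}

# Rotated (complete-records) bivariate evaluator: O(n) per iteration.
biv_eval_rotated <- function(dm1, dm2, K) {
  ids <- dm1$ids
  Ks <- unclass(K)[ids, ids]
  e <- eigen(Ks, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  y1 <- drop(crossprod(U, dm1$y)); y2 <- drop(crossprod(U, dm2$y))
  X1 <- crossprod(U, dm1$X); X2 <- crossprod(U, dm2$X)
  p1 <- ncol(X1); p2 <- ncol(X2)
  i1 <- seq_len(p1); i2 <- p1 + seq_len(p2)
  n <- length(d)
  # derivative structures: (E index, per-eigenvalue weight)
  wts <- list(d, d, d, rep(1, n), rep(1, n), rep(1, n))
  Es <- c(1L, 2L, 3L, 1L, 2L, 3L)  # 1 = E11, 2 = E12 (sym), 3 = E22

  function(theta) {
    v11 <- theta[1] * d + theta[4]
    v12 <- theta[2] * d + theta[5]
    v22 <- theta[3] * d + theta[6]
    det <- v11 * v22 - v12^2
    if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(NULL)
    m11 <- v22 / det; m12 <- -v12 / det; m22 <- v11 / det
    A <- rbind(cbind(crossprod(X1, X1 * m11), crossprod(X1, X2 * m12)),
               cbind(crossprod(X2, X1 * m12), crossprod(X2, X2 * m22)))
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    Ainv <- chol2inv(cA)
    rhs <- c(crossprod(X1, m11 * y1 + m12 * y2),
             crossprod(X2, m12 * y1 + m22 * y2))
    beta <- drop(Ainv %*% rhs)
    r1 <- y1 - drop(X1 %*% beta[i1])
    r2 <- y2 - drop(X2 %*% beta[i2])
    Py1 <- m11 * r1 + m12 * r2
    Py2 <- m12 * r1 + m22 * r2
    logL <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(cA))) +
                    sum(r1 * Py1 + r2 * Py2))
    R1 <- cbind(m11 * X1, m12 * X2)  # V^-1 X, trait-1 rows
    R2 <- cbind(m12 * X1, m22 * X2)  # V^-1 X, trait-2 rows
    Papply <- function(x1, x2) {
      w1 <- m11 * x1 + m12 * x2
      w2 <- m12 * x1 + m22 * x2
      gam <- Ainv %*% c(crossprod(X1, w1), crossprod(X2, w2))
      list(w1 - drop(R1 %*% gam), w2 - drop(R2 %*% gam))
    }
    vk_apply <- function(k, x1, x2) {
      c_ <- wts[[k]]
      switch(Es[k],
             list(c_ * x1, 0 * x2),
             list(c_ * x2, c_ * x1),
             list(0 * x1, c_ * x2))
    }
    tr <- quad <- numeric(6)
    u <- vector("list", 6)
    for (k in 1:6) {
      c_ <- wts[[k]]
      tr_v <- switch(Es[k], sum(c_ * m11), 2 * sum(c_ * m12),
                     sum(c_ * m22))
      sk <- vk_apply(k, R1, R2)  # V_k %*% (V^-1 X): matrices n x p
      Bk <- crossprod(R1, sk[[1]]) + crossprod(R2, sk[[2]])
      tr[k] <- tr_v - sum(Ainv * Bk)
      uk <- vk_apply(k, Py1, Py2)
      u[[k]] <- uk
      quad[k] <- sum(Py1 * uk[[1]] + Py2 * uk[[2]])
    }
    AI <- matrix(0, 6, 6)
    for (l in 1:6) {
      pu <- Papply(u[[l]][[1]], u[[l]][[2]])
      for (k in 1:l)
        AI[k, l] <- AI[l, k] <-
          0.5 * sum(u[[k]][[1]] * pu[[1]] + u[[k]][[2]] * pu[[2]])
    }
    list(logL = logL, grad = -0.5 * (tr - quad), AI = AI,
         quad = quad, tr = tr)
  }
}

# Dense bivariate evaluator for unequal sample sets (small n).
biv_eval_dense <- function(dm1, dm2, K) {
  ids_all <- union(dm1$ids, dm2$ids)
  Ks <- unclass(K)[ids_all, ids_all]
  t_r <- c(rep(1L, length(dm1$y)), rep(2L, length(dm2$y)))
  i_r <- c(match(dm1$ids, ids_all), match(dm2$ids, ids_all))
  y <- c(dm1$y, dm2$y)
  N <- length(y)
  X <- matrix(0, N, ncol(dm1$X) + ncol(dm2$X))
  X[t_r == 1L, seq_len(ncol(dm1$X))] <- dm1$X
  X[t_r == 2L, ncol(dm1$X) + seq_len(ncol(dm2$X))] <- dm2$X
  K_big <- Ks[i_r, i_r]
  D_big <- outer(i_r, i_r, "==") * 1
  Mask <- list(outer(t_r == 1L, t_r == 1L) * 1,
               (outer(t_r == 1L, t_r == 2L) | outer(t_r == 2L, t_r == 1L)) * 1,
               outer(t_r == 2L, t_r == 2L) * 1)
  Vk <- list(Mask[[1]] * K_big, Mask[[2]] * K_big, Mask[[3]] * K_big,
             Mask[[1]] * D_big, Mask[[2]] * D_big, Mask[[3]] * D_big)

  function(theta) {
    V <- theta[1] * Vk[[1]] + theta[2] * Vk[[2]] + theta[3] * Vk[[3]] +
      theta[4] * Vk[[4]] + theta[5] * Vk[[5]] + theta[6] * Vk[[6]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    A <- crossprod(X, ViX)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    Ainv <- chol2inv(cA)
    P <- Vi - ViX %*% Ainv %*% t(ViX)
    Py <- drop(P %*% y)
    logL <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cA))) +
                    sum(y * Py))
    tr <- quad <- numeric(6)
    u <- vector("list", 6)
    for (k in 1:6) {
      tr[k] <- sum(P * Vk[[k]])
      u[[k]] <- drop(Vk[[k]] %*% Py)
      quad[k] <- sum(Py * u[[k]])
    }
    AI <- matrix(0, 6, 6)
    for (l in 1:6) {
      pu <- drop(P %*% u[[l]])
      for (k in 1:l)
        AI[k, l] <- AI[l, k] <- 0.5 * sum(u[[k]] * pu)
    }
    list(logL = logL, grad = -0.5 * (tr - quad), AI = AI,
         quad = quad, tr = tr)
  }
}
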