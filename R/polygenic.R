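# Polygenic animal model: REML variance components, BLUP breeding values and
# GRAMMAR residuals.  All fits work in the eigenbasis of the relationship
# matrix (one decomposition, reused across traits and permutations).

resolve_eigen <- function(kinship, eig) {
  if (!is.null(eig)) return(eig)
  kinship_eigen(kinship)
}

# Profiled univariate REML log-likelihood at heritability h.
# V0 = h*D + (1-h)*I on the unit-variance scale; total variance and the
# intercept are profiled out analytically.
uni_profile_ll <- function(h, d, yt, xt) {
  n <- length(yt)
  v <- h * d + (1 - h)
  w <- 1 / v
  xx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / xx
  rss <- sum(w * (yt - xt * mu)^2)
  s2 <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xx) +
                  (n - 1) * (1 + log(2 * pi)))
  list(ll = ll, mu = mu, s2 = s2)
}

# Unprofiled REML log-likelihood in (sigma2_a, sigma2_e); used only for the
# observed-information standard errors.
uni_reml_ll_vc <- function(sa, se, d, yt, xt) {
  v <- sa * d + se
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  xx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / xx
  rss <- sum(w * (yt - xt * mu)^2)
  -0.5 * (sum(log(v)) + log(xx) + rss + (length(yt) - 1) * log(2 * pi))
}

#' Univariate REML fit of the polygenic animal model
#'
#' Fits \eqn{y = \mu + a + e}, \eqn{a \sim N(0, A\sigma^2_a)},
#' \eqn{e \sim N(0, I\sigma^2_e)} by restricted maximum likelihood, where A
#' is the genomic relationship matrix rescaled to mean diagonal 1 (see
#' [kinship_eigen()]).  The spectral decomposition of A reduces REML to a
#' one-dimensional profile likelihood in the heritability
#' \eqn{h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)}, maximised by Brent
#' search on (1e-6, 1-1e-6).
#'
#' @param y Numeric phenotype vector (finite, positive variance), aligned
#'   with the kinship individuals.
#' @param kinship A [compute_kinship()] result.
#' @param eig Optional precomputed [kinship_eigen()] decomposition, reused
#'   across traits and permutations.
#' @param tol Convergence tolerance on h2 (default 1e-8).
#' @return Object of class `varcomp`: `sigma2_a`, `sigma2_e`, `h2`,
#'   standard errors (observed information / profile curvature), the REML
#'   log-likelihood, the fitted intercept `mu`, and a `boundary` flag set
#'   when the estimate lies at 0 or 1.
#' @export
fit_univariate_reml <- function(y, kinship = NULL, eig = NULL, tol = 1e-8) {
  eig <- resolve_eigen(kinship, eig)
  y <- as.numeric(y)
  n <- length(y)
  if (n != length(eig$values))
    stop("fit_univariate_reml: phenotype and kinship dimensions differ")
  if (any(!is.finite(y))) stop("fit_univariate_reml: non-finite phenotype")
  if (stats::var(y) == 0) stop("fit_univariate_reml: phenotype has zero variance")
  d <- eig$values
  U <- eig$vectors
  yt <- as.vector(crossprod(U, y))
  xt <- as.vector(crossprod(U, rep(1, n)))
  opt <- stats::optimize(function(h) uni_profile_ll(h, d, yt, xt)$ll,
                         interval = c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = tol)
  h <- opt$maximum
  at <- uni_profile_ll(h, d, yt, xt)
  boundary <- h < 1e-4 || h > 1 - 1e-4
  sigma2_a <- h * at$s2
  sigma2_e <- (1 - h) * at$s2
  # observed information on (sigma2_a, sigma2_e) by central differences,
  # computed on the unit-variance scale so the numerics are indifferent to
  # the trait's measurement scale, then mapped back
  se_sa <- se_se <- se_h2 <- NA_real_
  if (!boundary) {
    tot <- at$s2
    yts <- yt / sqrt(tot)
    f <- function(p) uni_reml_ll_vc(p[1], p[2], d, yts, xt)
    H <- tryCatch(stats::optimHess(c(h, 1 - h), f), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se_sa <- sqrt(V[1, 1]) * tot
        se_se <- sqrt(V[2, 2]) * tot
        g <- c(1 - h, -h)  # d h2 / d(sa', se') at sa' + se' = 1
        vh <- drop(t(g) %*% V %*% g)
        if (vh > 0) se_h2 <- sqrt(vh)
      }
    }
  }
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e, h2 = h,
                 se_h2 = se_h2, se_sigma2_a = se_sa, se_sigma2_e = se_se,
                 loglik = at$ll, mu = at$mu, n = n,
                 boundary = boundary),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("varcomp: h2 = %.3f (se %.3f), sigma2_a = %.4g, sigma2_e = %.4g\n",
              x$h2, x$se_h2, x$sigma2_a, x$sigma2_e))
  cat(sprintf("  REML loglik %.3f%s\n", x$loglik,
              if (x$boundary) " [boundary estimate]" else ""))
  invisible(x)
}

#' GRAMMAR residuals: phenotype minus fitted mean and breeding value
#'
#' Computes BLUP additive values at the REML estimates and returns
#' \eqn{y^* = y - (\hat\mu + \hat a)}, the phenotype freed of the polygenic
#' family signal, which the GRAMMAR scan then regresses on SNP doses.
#' Algebraically \eqn{y^* = \hat\sigma^2_e V^{-1}(y-\hat\mu)} with
#' \eqn{V = \hat\sigma^2_a A + \hat\sigma^2_e I}; the GLS intercept makes
#' the residuals exactly zero-mean under \eqn{V^{-1}} weighting (and
#' zero-mean unweighted as well, since \eqn{1'V^{-1}(y-\hat\mu 1)=0}).
#'
#' @param y Phenotype vector used in the fit.
#' @param kinship,eig Relationship matrix or its [kinship_eigen()]
#'   decomposition (as in [fit_univariate_reml()]).
#' @param vc The [fit_univariate_reml()] result for this phenotype.
#' @return Object of class `residual_set`: `residuals`, `blup`, `mu`,
#'   `h2`, `ids`.
#' @export
grammar_residuals <- function(y, kinship = NULL, vc, eig = NULL) {
  eig <- resolve_eigen(kinship, eig)
  stopifnot(inherits(vc, "varcomp"))
  y <- as.numeric(y)
  n <- length(y)
  h <- vc$h2
  if (h > 1 - 1e-4)
    warning("grammar_residuals: h2 at the upper boundary; residuals are ",
            "near zero and the scan will have little power")
  d <- eig$values
  U <- eig$vectors
  yt <- as.vector(crossprod(U, y))
  xt <- as.vector(crossprod(U, rep(1, n)))
  w <- 1 / (h * d + (1 - h))
  mu <- sum(w * xt * yt) / sum(w * xt^2)
  ystar <- as.vector(U %*% ((1 - h) * w * (yt - xt * mu)))
  blup <- y - mu - ystar
  ids <- eig$ids %||% as.character(seq_len(n))
  names(ystar) <- names(blup) <- ids
  structure(list(residuals = ystar, blup = blup, mu = mu, h2 = h, ids = ids),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("residual_set: n = %d, h2 used = %.3f, sd(y*) = %.4g\n",
              length(x$residuals), x$h2, stats::sd(x$residuals)))
  invisible(x)
}

# --- bivariate REML ---------------------------------------------------------

chol2cov <- function(v) {
  L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
  L %*% t(L)
}

cov2chol_par <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

# Negative REML log-likelihood for the 2-trait model in the eigenbasis.
# Yt: n x 2 transformed phenotypes, Zt: n x p transformed fixed design
# (same design in both traits), d: eigenvalues.
biv_nll <- function(par, d, Yt, Zt) {
  Sa <- chol2cov(par[1:3])
  Se <- chol2cov(par[4:6])
  C11 <- d * Sa[1, 1] + Se[1, 1]
  C22 <- d * Sa[2, 2] + Se[2, 2]
  C12 <- d * Sa[1, 2] + Se[1, 2]
  det2 <- C11 * C22 - C12^2
  if (any(det2 <= 0) || any(C11 <= 0) || any(C22 <= 0)) return(1e10)
  W11 <- C22 / det2; W22 <- C11 / det2; W12 <- -C12 / det2
  p <- ncol(Zt); n <- nrow(Zt)
  A11 <- crossprod(Zt, Zt * W11)
  A12 <- crossprod(Zt, Zt * W12)
  A22 <- crossprod(Zt, Zt * W22)
  M <- rbind(cbind(A11, A12), cbind(A12, A22))
  b <- c(crossprod(Zt, W11 * Yt[, 1] + W12 * Yt[, 2]),
         crossprod(Zt, W12 * Yt[, 1] + W22 * Yt[, 2]))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  r1 <- Yt[, 1] - Zt %*% beta[seq_len(p)]
  r2 <- Yt[, 2] - Zt %*% beta[p + seq_len(p)]
  quad <- sum(W11 * r1^2 + 2 * W12 * r1 * r2 + W22 * r2^2)
  0.5 * (sum(log(det2)) + 2 * sum(log(diag(ch))) + quad +
           (2 * n - 2 * p) * log(2 * pi))
}

#' Bivariate REML fit: genetic and residual covariances for a trait pair
#'
#' Maximises the two-trait REML likelihood with additive covariance
#' \eqn{\Sigma_a \otimes A} and residual covariance \eqn{\Sigma_e \otimes I},
#' over a log-Cholesky parameterisation that enforces positive definite
#' components.  Working in the eigenbasis of A the likelihood factorises
#' over eigenvalues, so each evaluation is O(n).  Phenotypes are
#' standardised internally (results are mapped back), which makes the
#' optimiser indifferent to trait scale.
#'
#' @param y1,y2 Phenotype vectors for the two traits.
#' @param kinship,eig Relationship matrix or its precomputed
#'   [kinship_eigen()] decomposition.
#' @param covariates Optional numeric matrix of fixed covariates (e.g. SNP
#'   doses), applied to both traits; an intercept is always included.
#'   Collinear columns are dropped with a warning.
#' @param max_restarts Nelder-Mead restarts before the quasi-Newton polish
#'   (default 2).
#' @return Object of class `bivar_vc`: 2x2 `Sigma_a` and `Sigma_e`, the
#'   genetic correlation `r_g` (with delta-method `se_rg`), phenotypic
#'   correlation `r_p`, per-trait `h2`, REML `loglik`, the fixed-effect
#'   estimates, and a `degenerate` flag when |r| ~ 1.
#' @export
fit_bivariate_reml <- function(y1, y2, kinship = NULL, covariates = NULL,
                               eig = NULL, max_restarts = 2) {
  eig <- resolve_eigen(kinship, eig)
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  n <- length(eig$values)
  stopifnot(length(y1) == n, length(y2) == n)
  if (any(!is.finite(y1)) || any(!is.finite(y2)))
    stop("fit_bivariate_reml: non-finite phenotype")
  Z <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (ncol(covariates) > n / 2)
      stop("fit_bivariate_reml: more covariates than individuals/2")
    Z <- cbind(Z, covariates)
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      drop_idx <- qrz$pivot[-seq_len(qrz$rank)]
      warning(sprintf("fit_bivariate_reml: dropping %d collinear covariate(s)",
                      length(drop_idx)))
      Z <- Z[, qrz$pivot[seq_len(qrz$rank)], drop = FALSE]
    }
  }
  s1 <- stats::sd(y1); s2 <- stats::sd(y2)
  if (s1 == 0 || s2 == 0) stop("fit_bivariate_reml: zero-variance phenotype")
  ys <- cbind(y1 / s1, y2 / s2)
  U <- eig$vectors; d <- eig$values
  Yt <- crossprod(U, ys)
  Zt <- crossprod(U, Z)
  # starting values from univariate fits and the sample correlation
  f1 <- fit_univariate_reml(ys[, 1], eig = eig)
  f2 <- fit_univariate_reml(ys[, 2], eig = eig)
  r0 <- stats::cor(ys[, 1], ys[, 2]) * 0.7
  mk_start <- function(shrink) {
    Sa <- matrix(c(max(f1$sigma2_a, 1e-4), rep(r0 * shrink *
      sqrt(max(f1$sigma2_a, 1e-4) * max(f2$sigma2_a, 1e-4)), 2),
      max(f2$sigma2_a, 1e-4)), 2, 2)
    Se <- matrix(c(max(f1$sigma2_e, 1e-4), rep(r0 * shrink *
      sqrt(max(f1$sigma2_e, 1e-4) * max(f2$sigma2_e, 1e-4)), 2),
      max(f2$sigma2_e, 1e-4)), 2, 2)
    c(cov2chol_par(Sa), cov2chol_par(Se))
  }
  nll <- function(p) biv_nll(p, d, Yt, Zt)
  best <- NULL
  for (shrink in c(1, 0.3, 0)[seq_len(max_restarts + 1)]) {
    o <- stats::optim(mk_start(shrink), nll, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  o <- stats::optim(best$par, nll, method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  if (o$value > best$value) o <- best
  Sa <- chol2cov(o$par[1:3]); Se <- chol2cov(o$par[4:6])
  r_g <- Sa[1, 2] / sqrt(Sa[1, 1] * Sa[2, 2])
  Sp <- Sa + Se
  r_p <- Sp[1, 2] / sqrt(Sp[1, 1] * Sp[2, 2])
  degenerate <- abs(r_g) > 0.999 || abs(r_p) > 0.999
  if (degenerate) {
    # boundary optimum: the log-Cholesky surface is razor-thin here, so the
    # gradient criterion below is not meaningful
    warning("fit_bivariate_reml: correlation at the boundary (|r| ~ 1)")
  } else {
    grad <- vapply(seq_along(o$par), function(j) {
      h <- 1e-5
      pp <- o$par; pp[j] <- pp[j] + h
      pm <- o$par; pm[j] <- pm[j] - h
      (nll(pp) - nll(pm)) / (2 * h)
    }, numeric(1))
    if (sqrt(sum(grad^2)) > 1e-2 * (1 + abs(o$value)))
      stop(sprintf(
        "fit_bivariate_reml: no convergence (|grad| = %.3g at nll = %.4f; par = %s)",
        sqrt(sum(grad^2)), o$value, paste(signif(o$par, 4), collapse = ", ")))
  }
  g <- if (degenerate) NULL else
    tryCatch(stats::optimHess(o$par, nll), error = function(e) NULL)
  sc <- c(s1, s2)
  Sa_out <- Sa * outer(sc, sc)
  Se_out <- Se * outer(sc, sc)
  se_rg <- NA_real_
  if (!is.null(g) && !degenerate) {
    Vp <- tryCatch(solve(g), error = function(e) NULL)
    if (!is.null(Vp)) {
      rg_of <- function(p) {
        S <- chol2cov(p[1:3]); S[1, 2] / sqrt(S[1, 1] * S[2, 2])
      }
      gr <- vapply(seq_along(o$par), function(j) {
        h <- 1e-5
        pp <- o$par; pp[j] <- pp[j] + h
        pm <- o$par; pm[j] <- pm[j] - h
        (rg_of(pp) - rg_of(pm)) / (2 * h)
      }, numeric(1))
      v <- drop(t(gr) %*% Vp %*% gr)
      if (is.finite(v) && v > 0) se_rg <- sqrt(v)
    }
  }
  h2 <- c(Sa[1, 1] / Sp[1, 1], Sa[2, 2] / Sp[2, 2])
  structure(list(Sigma_a = Sa_out, Sigma_e = Se_out,
                 r_g = r_g, se_rg = se_rg, r_p = r_p, h2 = h2,
                 loglik = -o$value, n_covariates = ncol(Z) - 1,
                 degenerate = degenerate),
            class = "bivar_vc")
}

#' @export
print.bivar_vc <- function(x, ...) {
  cat(sprintf("bivar_vc: r_g = %.3f (se %.3f), r_p = %.3f, h2 = (%.3f, %.3f)\n",
              x$r_g, x$se_rg, x$r_p, x$h2[1], x$h2[2]))
  if (x$n_covariates > 0)
    cat(sprintf("  %d SNP covariate(s) fitted as fixed effects\n",
                x$n_covariates))
  invisible(x)
}

#' Bivariate REML refit with SNP doses as fixed covariates
#'
#' Refits the two-trait animal model with candidate SNP doses included as
#' fixed effects, to quantify how much of the genetic correlation the
#' chosen loci account for.  Monomorphic columns are dropped (warning);
#' collinear columns are handled by [fit_bivariate_reml()].
#'
#' @param y1,y2 Phenotype vectors.
#' @param kinship,eig Relationship matrix or its decomposition.
#' @param snp_doses Matrix of allele doses (individuals x SNPs); may be
#'   empty/NULL, in which case this is identical to [fit_bivariate_reml()].
#' @return A `bivar_vc` object (see [fit_bivariate_reml()]).
#' @export
refit_with_snp_covariates <- function(y1, y2, kinship = NULL, snp_doses = NULL,
                                      eig = NULL) {
  if (!is.null(snp_doses)) {
    snp_doses <- as.matrix(snp_doses)
    if (ncol(snp_doses) == 0) snp_doses <- NULL
  }
  if (!is.null(snp_doses)) {
    v <- apply(snp_doses, 2, stats::var)
    if (any(v == 0)) {
      warning(sprintf("refit_with_snp_covariates: dropping %d monomorphic SNP(s)",
                      sum(v == 0)))
      snp_doses <- snp_doses[, v > 0, drop = FALSE]
      if (ncol(snp_doses) == 0) snp_doses <- NULL
    }
  }
  fit_bivariate_reml(y1, y2, kinship = kinship, covariates = snp_doses,
                     eig = eig)
}
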