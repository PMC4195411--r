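make_fixture <- function(seed, n = 300, snps = 120, ...) {
  cfg <- small_config(seed = seed, n = n, snps = snps, ...)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  K <- suppressWarnings(compute_kinship(g))
  list(cfg = cfg, g = g, ph = ph, K = K, eig = kinship_eigen(K))
}

test_that("profile REML matches a dense-matrix likelihood oracle", {
  fx <- make_fixture(31, n = 12, snps = 80)
  y <- fx$ph$trait1
  A <- fx$K$values / mean(diag(fx$K$values))
  fit <- fit_univariate_reml(y, eig = fx$eig)
  expect_equal(fit$loglik, dense_reml_ll(fit$h2, y, A), tolerance = 1e-6)
  grid <- seq(0.02, 0.98, by = 0.04)
  dense <- vapply(grid, dense_reml_ll, numeric(1), y = y, A = A)
  expect_true(all(fit$loglik >= dense - 1e-6))
  # unimodality of the profile on this fixture: one sign change in the
  # first differences
  expect_lte(sum(abs(diff(sign(diff(dense))))) / 2, 1)
})

test_that("REML estimates are invariant to phenotype rescaling", {
  fx <- make_fixture(32, n = 150, snps = 80)
  f1 <- fit_univariate_reml(fx$ph$trait2, eig = fx$eig)
  f2 <- fit_univariate_reml(fx$ph$trait2 * 37.5, eig = fx$eig)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(f2$sigma2_a, f1$sigma2_a * 37.5^2, tolerance = 1e-3)
  fb1 <- fit_bivariate_reml(fx$ph$trait1, fx$ph$trait2, eig = fx$eig)
  fb2 <- fit_bivariate_reml(fx$ph$trait1 * 5, fx$ph$trait2 / 3, eig = fx$eig)
  expect_equal(fb1$r_g, fb2$r_g, tolerance = 1e-4)
})

test_that("pure-noise phenotypes drive the heritability to zero", {
  fx <- make_fixture(33, n = 200, snps = 100)
  h2s <- vapply(1:8, function(i) {
    set.seed(400 + i)
    fit_univariate_reml(rnorm(200), eig = fx$eig)$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.12)
})

test_that("errors on degenerate phenotype input", {
  fx <- make_fixture(34, n = 50, snps = 60)
  expect_error(fit_univariate_reml(rep(1, 50), eig = fx$eig), "variance")
  y <- rnorm(50); y[3] <- NA
  expect_error(fit_univariate_reml(y, eig = fx$eig), "non-finite")
})

test_that("GRAMMAR residuals equal the closed-form V-inverse expression", {
  fx <- make_fixture(35, n = 10, snps = 60)
  y <- fx$ph$trait1
  fit <- fit_univariate_reml(y, eig = fx$eig)
  rs <- grammar_residuals(y, vc = fit, eig = fx$eig)
  A <- fx$K$values / mean(diag(fx$K$values))
  V <- fit$sigma2_a * A + fit$sigma2_e * diag(10)
  Vi <- solve(V)
  one <- rep(1, 10)
  mu <- drop(t(one) %*% Vi %*% y) / drop(t(one) %*% Vi %*% one)
  oracle <- fit$sigma2_e * drop(Vi %*% (y - mu))
  expect_equal(unname(rs$residuals), unname(oracle), tolerance = 1e-10)
  expect_lt(abs(mean(rs$residuals)), 1e-9)
  expect_equal(unname(rs$residuals + rs$blup + rs$mu), y, tolerance = 1e-10)
})

test_that("zero additive variance reduces residuals to centered phenotypes", {
  fx <- make_fixture(36, n = 40, snps = 60)
  y <- fx$ph$trait3
  vc0 <- structure(list(sigma2_a = 0, sigma2_e = var(y), h2 = 0,
                        boundary = TRUE), class = "varcomp")
  rs <- grammar_residuals(y, vc = vc0, eig = fx$eig)
  expect_equal(unname(rs$residuals), y - mean(y), tolerance = 1e-10)
})

test_that("GRAMMAR correction strips the polygenic signal", {
  fx <- make_fixture(37, n = 400, snps = 150)
  cmp <- attr(fx$ph, "components")
  y <- fx$ph$trait1
  fit <- fit_univariate_reml(y, eig = fx$eig)
  rs <- grammar_residuals(y, vc = fit, eig = fx$eig)
  e_true <- cmp$residual[, 1]
  expect_gt(cor(rs$residuals, e_true), cor(y, e_true))
})

test_that("identical traits give a boundary genetic correlation", {
  fx <- make_fixture(38, n = 120, snps = 80)
  y <- fx$ph$trait1
  expect_warning(fb <- fit_bivariate_reml(y, y + 0, eig = fx$eig),
                 "boundary")
  expect_gt(fb$r_g, 0.99)
  expect_gt(fb$r_p, 0.99)
  expect_true(fb$degenerate)
})

test_that("bivariate REML recovers a strong positive genetic correlation", {
  fx <- make_fixture(39, n = 400, snps = 150)
  fb <- fit_bivariate_reml(fx$ph$trait1, fx$ph$trait2, eig = fx$eig)
  expect_gt(fb$r_g, 0.6)
  expect_lt(fb$r_g, 1.0)
  expect_gt(fb$r_p, 0.7)
})

test_that("refit with no covariates reproduces the base fit", {
  fx <- make_fixture(40, n = 150, snps = 80)
  base <- fit_bivariate_reml(fx$ph$trait1, fx$ph$trait2, eig = fx$eig)
  re <- refit_with_snp_covariates(fx$ph$trait1, fx$ph$trait2,
                                  snp_doses = NULL, eig = fx$eig)
  expect_equal(re$r_g, base$r_g, tolerance = 1e-8)
  expect_equal(re$loglik, base$loglik, tolerance = 1e-8)
})

test_that("fitting a shared QTL as fixed effect lowers r_g; a null SNP does not", {
  rg_mat <- diag(3); rg_mat[1, 2] <- rg_mat[2, 1] <- 0.5
  rp_mat <- diag(3); rp_mat[1, 2] <- rp_mat[2, 1] <- 0.5
  seeds <- 51:55
  d_causal <- numeric(length(seeds)); d_null <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    fx <- make_fixture(seeds[i], n = 300, snps = 100,
                       genetic_correlations = rg_mat,
                       phenotypic_correlations = rp_mat,
                       qtl_list = list(qtl_spec(1, 50, c(0.45, 0.45, 0))))
    causal <- which(fx$g$map$chr == 1)[which.min(abs(
      fx$g$map$pos[fx$g$map$chr == 1] - 50))]
    base <- fit_bivariate_reml(fx$ph$trait1, fx$ph$trait2, eig = fx$eig)
    re_c <- refit_with_snp_covariates(fx$ph$trait1, fx$ph$trait2,
      snp_doses = fx$g$doses[, causal, drop = FALSE], eig = fx$eig)
    null_snp <- which(fx$g$map$chr == 5)[10]
    re_n <- refit_with_snp_covariates(fx$ph$trait1, fx$ph$trait2,
      snp_doses = fx$g$doses[, null_snp, drop = FALSE], eig = fx$eig)
    d_causal[i] <- re_c$r_g - base$r_g
    d_null[i] <- re_n$r_g - base$r_g
  }
  expect_lt(mean(d_causal), 0)
  expect_lt(abs(mean(d_null)), 0.03)
})

test_that("too many covariates is an error", {
  fx <- make_fixture(41, n = 40, snps = 60)
  expect_error(suppressWarnings(
    refit_with_snp_covariates(fx$ph$trait1, fx$ph$trait2,
      snp_doses = fx$g$doses[, 1:30], eig = fx$eig)), "covariates")
})
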