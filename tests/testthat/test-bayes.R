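test_that("residual scaling gives exact zero mean and unit variance", {
  expect_equal(scale_residuals(matrix(c(1, 2, 3))), matrix(c(-1, 0, 1)))
  set.seed(90)
  Y <- matrix(rnorm(60, 5, 3), 20, 3)
  Z <- scale_residuals(Y)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, var)), rep(1, 3), tolerance = 1e-12)
  # already standardized input is (numerically) unchanged
  expect_equal(scale_residuals(Z), Z, tolerance = 1e-12)
  Y[, 2] <- 7
  expect_error(scale_residuals(Y), "zero-variance")
})

test_that("the degenerate V = 0 prior gives a Bayes factor of exactly 0", {
  set.seed(91)
  Y <- scale_residuals(matrix(rnorm(45), 15, 3))
  d <- rbinom(15, 2, 0.5)
  pr0 <- prior_spec(v = 0)
  expect_identical(bayes_factor(Y, d, pr0), 0)
  cc <- d - mean(d)
  expect_equal(log_marginal_likelihood(Y, cc, pr0),
               log_marginal_likelihood(Y, NULL, pr0), tolerance = 1e-12)
})

test_that("q = 1 closed form equals the scalar conjugate oracle", {
  set.seed(92)
  y <- rnorm(10)
  d <- rbinom(10, 2, 0.4)
  cc <- d - mean(d)
  pr <- prior_spec(df = 6, scale = 4, v = 0.02)
  expect_equal(log_marginal_likelihood(matrix(y), cc, pr),
               scalar_conjugate_lml(y, cc, df = 6, scale = 4, v = 0.02),
               tolerance = 1e-10)
  expect_equal(log_marginal_likelihood(matrix(y), NULL, pr),
               scalar_conjugate_lml(y, NULL, df = 6, scale = 4),
               tolerance = 1e-10)
  # nonzero prior mean
  prm <- prior_spec(df = 7, scale = 2, mean = 0.3, v = 0.05)
  expect_equal(log_marginal_likelihood(matrix(y), cc, prm),
               scalar_conjugate_lml(y, cc, df = 7, scale = 2, v = 0.05,
                                    mean = 0.3),
               tolerance = 1e-10)
})

test_that("closed form equals Monte-Carlo integration on small fixtures", {
  pr <- prior_spec()
  set.seed(93)
  Y2 <- matrix(rnorm(12), 6, 2)
  C2 <- c(0, 1, 2, 1, 0, 2); C2 <- C2 - mean(C2)
  Y3 <- matrix(rnorm(24), 8, 3)
  C3 <- rbinom(8, 2, 0.5); C3 <- C3 - mean(C3)
  cases <- list(list(Y = Y2, C = C2), list(Y = Y2, C = NULL),
                list(Y = Y3, C = C3))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    mc <- mc_log_marginal(cs$Y, cs$C, pr, ndraw = 1e5, seed = 200 + i)
    cf <- log_marginal_likelihood(cs$Y, cs$C, pr)
    expect_lt(abs(cf - mc$lml), 3 * mc$se)
  }
})

test_that("log10 BF is invariant to allele flips under a zero prior mean", {
  set.seed(94)
  Y <- scale_residuals(matrix(rnorm(90), 30, 3))
  d <- rbinom(30, 2, 0.3)
  expect_equal(bayes_factor(Y, d), bayes_factor(Y, 2 - d), tolerance = 1e-10)
})

test_that("null data carry a negative median log10 BF (Occam penalty)", {
  set.seed(95)
  bfs <- vapply(1:100, function(i) {
    Y <- scale_residuals(matrix(rnorm(200 * 3), 200, 3))
    d <- rbinom(200, 2, 0.5)
    bayes_factor(Y, d)
  }, numeric(1))
  expect_lt(median(bfs), 0)
})

test_that("log10 BF increases with the true effect size", {
  set.seed(96)
  mean_bf <- vapply(c(0, 0.25, 0.5), function(b) {
    mean(vapply(1:6, function(i) {
      d <- rbinom(300, 2, 0.5)
      Y <- matrix(rnorm(900), 300, 3) + b * d
      bayes_factor(scale_residuals(Y), d)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_bf) > 0))
})

test_that("a strong pleiotropic QTL exceeds the suggestive threshold", {
  bfp <- vapply(1:10, function(i) {
    cfg <- sim_config(n_individuals = 600, snps_per_chromosome = 80,
                      n_founder_haplotypes = 80, n_generations = 3,
                      founder_freq_range = c(0.3, 0.7),
                      qtl_list = list(qtl_spec(1, 50, c(0.4, 0.4, -0.4))),
                      seed = 8800 + i)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    eig <- kinship_eigen(suppressWarnings(compute_kinship(g)))
    rs <- lapply(c("trait1", "trait2", "trait3"), function(tr) {
      vc <- fit_univariate_reml(ph[[tr]], eig = eig)
      grammar_residuals(ph[[tr]], vc = vc, eig = eig)
    })
    causal <- which(g$map$chr == 1 & abs(g$map$pos - 50) < 0.01)
    bayes_factor(scale_residuals(rs), g$doses[, causal])
  }, numeric(1))
  expect_gte(sum(bfp >= 3), 9)
})

test_that("mv_scan matches per-SNP bayes_factor and flags monomorphics", {
  g <- tiny_genotypes(80, 30, seed = 97)
  g$doses[, 5] <- 2  # force one monomorphic SNP
  set.seed(98)
  Y <- matrix(rnorm(240), 80, 3)
  res <- mv_scan(Y, g)
  expect_equal(nrow(res), 30)
  Ys <- scale_residuals(Y)
  for (k in c(1, 9, 22)) {
    expect_equal(res$log10_bf[res$snp == g$map$snp[k]],
                 bayes_factor(Ys, g$doses[, k]), tolerance = 1e-8)
  }
  expect_true(is.na(res$log10_bf[res$snp == g$map$snp[5]]))
  # general-prior-mean path agrees with the per-SNP route too
  prm <- prior_spec(mean = 0.1)
  resm <- mv_scan(Y, g, prior = prm)
  expect_equal(resm$log10_bf[resm$snp == g$map$snp[9]],
               bayes_factor(Ys, g$doses[, 9], prm), tolerance = 1e-8)
})

test_that("Bayes-factor classification applies the threshold grades", {
  expect_equal(classify_bf(0), "none")
  expect_equal(classify_bf(c(-2, 3.1, 7)), c("none", "suggestive",
                                             "significant"))
  expect_true(is.na(classify_bf(NA_real_)))
  expect_error(classify_bf(1, suggestive = 5, significant = 3), "suggestive")
  # the reported multivariate hits are all at least suggestive under the
  # default grades; the strongest is significant
  rep_bf <- reported_bayes_hits()
  cls <- classify_bf(rep_bf$log10_bf)
  expect_true(all(cls %in% c("suggestive", "significant")))
  expect_equal(classify_bf(min(rep_bf$log10_bf)), "suggestive")
  expect_equal(classify_bf(max(rep_bf$log10_bf)), "significant")
})

test_that("prior specification is validated", {
  expect_error(prior_spec(v = -1))
  expect_error(prior_spec(scale = -2))
  expect_error(prior_spec(scale = matrix(c(1, 2, 2, 1), 2)), "positive definite")
  set.seed(99)
  Y <- matrix(rnorm(20), 10, 2)
  expect_error(log_marginal_likelihood(Y, prior = prior_spec(df = 0.5)),
               "df")
  expect_error(log_marginal_likelihood(matrix(rnorm(4), 2, 2)), "n > q")
})
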