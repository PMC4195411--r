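test_that("single-SNP regression matches hand and closed-form oracles", {
  # residuals orthogonal to dose: exact null
  r <- snp_regression(c(1, -1, 1, -1), c(0, 0, 2, 2))
  expect_equal(r$effect, 0)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  # OLS slope by hand: sum((g - gbar)(y - ybar)) / sum((g - gbar)^2) = 1/2
  r <- snp_regression(c(1, 2, 2), c(0, 1, 2))
  expect_equal(r$effect, 0.5, tolerance = 1e-12)
  # random instance vs textbook normal-equations oracle
  set.seed(61)
  y <- rnorm(50)
  g <- rbinom(50, 2, 0.4)
  r <- snp_regression(y, g)
  X <- cbind(1, g)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (50 - 2)
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(r$effect, beta[2], tolerance = 1e-10)
  expect_equal(r$se, se, tolerance = 1e-10)
  expect_equal(r$chi2, (beta[2] / se)^2, tolerance = 1e-10)
  # monomorphic: flagged NA
  expect_true(is.na(snp_regression(y, rep(2, 50))$chi2))
  expect_error(snp_regression(y, g[-1]), "length mismatch")
})

test_that("chi2 is invariant to residual shifts and allele flips", {
  set.seed(62)
  y <- rnorm(40)
  g <- rbinom(40, 2, 0.5)
  r0 <- snp_regression(y, g)
  r_shift <- snp_regression(y + 100, g)
  r_flip <- snp_regression(y, 2 - g)
  expect_equal(r_shift$chi2, r0$chi2, tolerance = 1e-9)
  expect_equal(r_flip$chi2, r0$chi2, tolerance = 1e-9)
  expect_equal(r_flip$effect, -r0$effect, tolerance = 1e-12)
})

test_that("genome_scan emits one ordered record per SNP", {
  g <- tiny_genotypes(60, 25, seed = 63, chr = rep(1:5, each = 5))
  set.seed(64)
  y <- rnorm(60)
  sc <- genome_scan(y, g, label = "t")
  expect_equal(nrow(sc), 25)
  expect_false(is.unsorted(order(sc$chr, sc$pos)))
  # per-SNP agreement with snp_regression
  for (k in c(1, 7, 25)) {
    one <- snp_regression(y, g$doses[, sc$snp[k]])
    expect_equal(sc$chi2[k], one$chi2, tolerance = 1e-10)
    expect_equal(sc$effect[k], one$effect, tolerance = 1e-10)
  }
  # all-zero residuals: every statistic zero
  sc0 <- genome_scan(rep(0, 60), g)
  expect_true(all(sc0$chi2 == 0))
  # ID mismatch is named
  bad <- rnorm(60)
  names(bad) <- sprintf("x%03d", 1:60)
  rs <- structure(list(residuals = bad), class = "residual_set")
  expect_error(genome_scan(rs, g), "mismatch")
})

test_that("the scan localises a strong simulated QTL", {
  hits <- 0
  for (seed in 71:75) {
    cfg <- small_config(seed = seed, n = 300, snps = 200,
                        founder_freq_range = c(0.3, 0.7),
                        qtl_list = list(qtl_spec(2, 50, c(0.5, 0, 0))))
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    eig <- kinship_eigen(suppressWarnings(compute_kinship(g)))
    vc <- fit_univariate_reml(ph$trait1, eig = eig)
    rs <- grammar_residuals(ph$trait1, vc = vc, eig = eig)
    sc <- genome_scan(rs, g, label = "trait1")
    top <- sc[which.max(sc$chi2), ]
    if (top$chr == 2 && abs(top$pos - 50) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("GRAMMAR is conservative on polygenic null data", {
  cfg <- small_config(seed = 77, n = 300, snps = 150, qtl_list = list())
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  eig <- kinship_eigen(suppressWarnings(compute_kinship(g)))
  means <- vapply(c("trait1", "trait2", "trait3"), function(tr) {
    vc <- fit_univariate_reml(ph[[tr]], eig = eig)
    rs <- grammar_residuals(ph[[tr]], vc = vc, eig = eig)
    mean(genome_scan(rs, g)$chi2, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(means), 1.05)
})

test_that("permutation threshold machinery: errors and degenerate null", {
  g <- tiny_genotypes(30, 10, seed = 80)
  set.seed(81)
  y <- rnorm(30)
  expect_error(permutation_threshold(y, g, B = 10, alpha = 0.05, seed = 1),
               "B \\* alpha|at least 20")
  expect_error(permutation_threshold(y, g, B = 100, alpha = 0.005, seed = 1),
               "B \\* alpha")
  # constant null: same permutation repeated -> every max identical
  perm1 <- sample(30)
  perms <- matrix(rep(perm1, 50), nrow = 50, byrow = TRUE)
  null <- permutation_threshold(y, g, alpha = 0.05, perms = perms)
  cmax <- null$max_chi2[1]
  expect_true(all(null$max_chi2 == cmax))
  expect_equal(null$threshold, cmax)
  expect_equal(perm_pvalue(null, cmax + 1), 1 / 51)
  expect_equal(perm_pvalue(null, cmax - 1e-9), 1)
})

test_that("permutation threshold matches exhaustive enumeration exactly", {
  g <- geno_from_doses(c(0, 1, 2, 1, 0), c(2, 2, 0, 1, 1), c(1, 0, 1, 2, 2))
  y <- c(0.3, -1.2, 0.7, 2.1, -0.9)
  perms <- all_perms(1:5)  # all 120 distinct permutations
  null <- permutation_threshold(y, g, alpha = 0.05, perms = perms)
  # independent oracle: per-permutation max via snp_regression loops
  oracle_max <- apply(perms, 1, function(ix) {
    max(vapply(1:3, function(k) snp_regression(y[ix], g$doses[, k])$chi2,
               numeric(1)))
  })
  expect_equal(sort(null$max_chi2), sort(oracle_max), tolerance = 1e-12)
  k <- floor(0.05 * (120 + 1))
  expect_equal(null$threshold, sort(oracle_max, decreasing = TRUE)[k])
})

test_that("the permutation test is calibrated on exchangeable residuals", {
  # iid residuals satisfy the permutation null exactly, so the genome-wide
  # test should reject at ~alpha (GRAMMAR residuals on related individuals
  # are deflated below this; see the conservativeness test above)
  g <- tiny_genotypes(150, 300, seed = 86, chr = rep(1:5, each = 60))
  set.seed(87)
  rej <- vapply(1:200, function(i) {
    y <- rnorm(150)
    null <- permutation_threshold(y, g, B = 100, alpha = 0.05,
                                  seed = 20000 + i)
    obs <- max(genome_scan(y, g)$chi2, na.rm = TRUE)
    perm_pvalue(null, obs) <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("the threshold is monotone non-increasing in alpha", {
  g <- tiny_genotypes(40, 30, seed = 83)
  set.seed(84)
  y <- rnorm(40)
  th <- vapply(c(0.05, 0.10, 0.25, 0.5), function(a)
    permutation_threshold(y, g, B = 100, alpha = a, seed = 9)$threshold,
    numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("clumping reproduces the ten reported QTL regions", {
  hits <- reported_grammar_hits()
  traits <- hits[hits$label %in% c("trait1", "trait2", "trait3"), ]
  regions <- clump_qtl(traits, merge_distance = 10)
  expect_equal(nrow(regions), 10)
  expect_equal(sort(unique(regions$chr)), 1:4)
  expect_equal(sum(regions$label == "trait1"), 2)
  expect_equal(sum(regions$label == "trait2"), 3)
  expect_equal(sum(regions$label == "trait3"), 5)
  # trait-3 member spans as printed
  t3 <- regions[regions$label == "trait3", ]
  spans <- t3[order(t3$chr, t3$span_start), c("span_start", "span_end")]
  expect_equal(unname(as.matrix(spans)),
               matrix(c(58.00, 58.85, 84.05, 84.90, 79.15, 79.20,
                        2.15, 2.15, 36.85, 36.85), ncol = 2, byrow = TRUE))
})

test_that("clumping is order-invariant, disjoint, and handles edge cases", {
  set.seed(85)
  sig <- data.frame(label = "s", chr = c(1, 1, 1, 2, 2),
                    pos = c(5, 12, 40, 3, 90), chi2 = c(9, 12, 30, 15, 20))
  r1 <- clump_qtl(sig)
  r2 <- clump_qtl(sig[sample(nrow(sig)), ])
  expect_equal(r1, r2)
  # chaining: 5 and 12 merge (gap 7 <= 10), 40 separate
  expect_equal(nrow(r1[r1$chr == 1, ]), 2)
  # member spans disjoint within chromosome/label
  for (cc in unique(r1$chr)) {
    rc <- r1[r1$chr == cc, ]
    rc <- rc[order(rc$span_start), ]
    if (nrow(rc) > 1)
      expect_true(all(rc$span_start[-1] > rc$span_end[-nrow(rc)]))
  }
  # single SNP: region centred on it
  one <- clump_qtl(data.frame(chr = 3, pos = 50), merge_distance = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 45)
  expect_equal(one$end, 55)
  expect_equal(one$peak_pos, 50)
  # clipping to chromosome bounds
  edge <- clump_qtl(data.frame(chr = 1, pos = 2), merge_distance = 10,
                    chromosome_length = 100)
  expect_equal(edge$start, 0)
  # empty input
  expect_equal(nrow(clump_qtl(NULL)), 0)
  expect_equal(nrow(clump_qtl(data.frame(chr = integer(), pos = numeric()))), 0)
})
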