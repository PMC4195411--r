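# Independent oracles used by the unit and acceptance tests.

# Brute-force nested-loop genomic kinship (allelic 0/0.5/1 scale over
# p(1-p)), deliberately naive.
kinship_bruteforce <- function(doses) {
  n <- nrow(doses); m <- ncol(doses)
  g <- doses / 2
  p <- colMeans(doses) / 2
  keep <- p > 0 & p < 1
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in which(keep))
      s <- s + (g[i, k] - p[k]) * (g[j, k] - p[k]) / (p[k] * (1 - p[k]))
    G[i, j] <- s / sum(keep)
  }
  G
}

# Dense-matrix REML log-likelihood at a given heritability, profiling the
# intercept and the total variance (matches the definition the package
# reports, but via explicit solve() on the full covariance).
dense_reml_ll <- function(h, y, A) {
  n <- length(y)
  V <- h * A + (1 - h) * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  xx <- drop(t(one) %*% Vi %*% one)
  mu <- drop(t(one) %*% Vi %*% y) / xx
  r <- y - mu
  rss <- drop(t(r) %*% Vi %*% r)
  s2 <- rss / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus[1] + log(xx) +
            (n - 1) * (1 + log(2 * pi)))
}

# Scalar (q = 1) conjugate marginal likelihood: multivariate-t density of y
# under sigma2 ~ IG(df/2, scale/2), beta | sigma2 ~ N(mean, v * sigma2).
scalar_conjugate_lml <- function(y, C = NULL, df, scale, v = 0.02, mean = 0) {
  n <- length(y)
  S <- diag(n)
  mu <- rep(0, n)
  if (!is.null(C)) {
    S <- S + v * tcrossprod(C)
    mu <- C * mean
  }
  S <- (scale / df) * S
  r <- y - mu
  q <- drop(t(r) %*% solve(S) %*% r)
  lgamma((df + n) / 2) - lgamma(df / 2) - (n / 2) * log(df * pi) -
    0.5 * determinant(S)$modulus[1] - ((df + n) / 2) * log1p(q / df)
}

# Monte-Carlo integration of the matrix-normal inverse-Wishart marginal
# likelihood: Sigma ~ IW(df, Q), b | Sigma ~ N(mean, v Sigma), likelihood
# averaged over prior draws.  Vectorised over draws for q <= 3.  Returns
# the log marginal likelihood and its MC standard error.
mc_log_marginal <- function(Y, C = NULL, prior, ndraw = 1e5, seed = 1) {
  set.seed(seed)
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  Q <- if (is.matrix(prior$scale)) prior$scale else diag(prior$scale, q)
  W <- stats::rWishart(ndraw, prior$df, solve(Q))  # W = Sigma^{-1} draws
  YtY <- crossprod(Y)
  # logdet(W) and the trace term tr(W Y'Y), componentwise over draws
  if (q == 1) {
    w11 <- W[1, 1, ]
    ldetW <- log(w11)
    trWY <- w11 * YtY[1, 1]
  } else if (q == 2) {
    w11 <- W[1, 1, ]; w12 <- W[1, 2, ]; w22 <- W[2, 2, ]
    ldetW <- log(w11 * w22 - w12^2)
    trWY <- w11 * YtY[1, 1] + 2 * w12 * YtY[1, 2] + w22 * YtY[2, 2]
  } else if (q == 3) {
    w11 <- W[1, 1, ]; w12 <- W[1, 2, ]; w13 <- W[1, 3, ]
    w22 <- W[2, 2, ]; w23 <- W[2, 3, ]; w33 <- W[3, 3, ]
    ldetW <- log(w11 * (w22 * w33 - w23^2) - w12 * (w12 * w33 - w23 * w13) +
                   w13 * (w12 * w23 - w22 * w13))
    trWY <- w11 * YtY[1, 1] + w22 * YtY[2, 2] + w33 * YtY[3, 3] +
      2 * (w12 * YtY[1, 2] + w13 * YtY[1, 3] + w23 * YtY[2, 3])
  } else stop("mc oracle supports q <= 3")
  tr_term <- trWY
  if (!is.null(C)) {
    C <- as.numeric(C)
    a <- as.numeric(crossprod(C, Y))   # c'Y, length q
    cc <- sum(C^2)
    # draw b | Sigma ~ N(mean, v Sigma) via b = M + sqrt(v) T^{-1} z with
    # W = T'T (upper-triangular T)
    z <- matrix(rnorm(ndraw * q), q, ndraw)
    if (q == 1) {
      t11 <- sqrt(w11)
      b1 <- prior$mean + sqrt(prior$v) * z[1, ] / t11
      bWa <- w11 * b1 * a[1]
      bWb <- w11 * b1^2
      b <- rbind(b1)
    } else if (q == 2) {
      t11 <- sqrt(w11); t12 <- w12 / t11; t22 <- sqrt(w22 - t12^2)
      b2 <- z[2, ] / t22
      b1 <- (z[1, ] - t12 * b2) / t11
      b1 <- prior$mean + sqrt(prior$v) * b1
      b2 <- prior$mean + sqrt(prior$v) * b2
      bWa <- (w11 * b1 + w12 * b2) * a[1] + (w12 * b1 + w22 * b2) * a[2]
      bWb <- w11 * b1^2 + 2 * w12 * b1 * b2 + w22 * b2^2
    } else {
      t11 <- sqrt(w11); t12 <- w12 / t11; t13 <- w13 / t11
      t22 <- sqrt(w22 - t12^2); t23 <- (w23 - t12 * t13) / t22
      t33 <- sqrt(w33 - t13^2 - t23^2)
      b3 <- z[3, ] / t33
      b2 <- (z[2, ] - t23 * b3) / t22
      b1 <- (z[1, ] - t12 * b2 - t13 * b3) / t11
      b1 <- prior$mean + sqrt(prior$v) * b1
      b2 <- prior$mean + sqrt(prior$v) * b2
      b3 <- prior$mean + sqrt(prior$v) * b3
      Wb1 <- w11 * b1 + w12 * b2 + w13 * b3
      Wb2 <- w12 * b1 + w22 * b2 + w23 * b3
      Wb3 <- w13 * b1 + w23 * b2 + w33 * b3
      bWa <- Wb1 * a[1] + Wb2 * a[2] + Wb3 * a[3]
      bWb <- b1 * Wb1 + b2 * Wb2 + b3 * Wb3
    }
    tr_term <- trWY - 2 * bWa + cc * bWb
  }
  ll <- -(n * q / 2) * log(2 * pi) + (n / 2) * ldetW - 0.5 * tr_term
  mx <- max(ll)
  w <- exp(ll - mx)
  lml <- mx + log(mean(w))
  se <- sd(w) / (sqrt(ndraw) * mean(w))
  list(lml = lml, se = se)
}
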