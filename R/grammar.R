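# GRAMMAR association scan: OLS of mixed-model residuals on SNP allele
# doses, permutation-based genome-wide significance, and clumping of
# significant SNPs into QTL regions.

POS_TOL <- 1e-6  # Mb tolerance on position equality

#' Single-SNP residual regression
#'
#' Ordinary least squares of GRAMMAR residuals on an allele-dose vector:
#' \eqn{y^* = \mu^* + k g + e^*}.  The reported 1-df chi-square is
#' \eqn{(k/\mathrm{se}(k))^2}, with the nominal p-value from the
#' chi-square upper tail.
#'
#' @param residuals Numeric residual vector.
#' @param doses Allele doses (0/1/2), same length.
#' @return List with `effect`, `se`, `chi2`, `p`.  A SNP monomorphic in
#'   the sample yields `NA` statistics.
#' @export
snp_regression <- function(residuals, doses) {
  if (length(residuals) != length(doses))
    stop("snp_regression: length mismatch")
  ok <- !is.na(residuals) & !is.na(doses)
  y <- residuals[ok]; g <- doses[ok]
  n <- length(y)
  if (n < 3) stop("snp_regression: fewer than 3 complete observations")
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0)
    return(list(effect = NA_real_, se = NA_real_, chi2 = NA_real_,
                p = NA_real_))
  yc <- y - mean(y)
  sxy <- sum(g * yc)
  k <- sxy / sxx
  rss <- sum(yc^2) - sxy^2 / sxx
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  chi2 <- if (se > 0) (k / se)^2 else if (k == 0) 0 else Inf
  list(effect = k, se = se, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Vectorised chi-square over all SNPs.  `sxx`, `dm` precomputable.
scan_stats <- function(y, D, dm = colMeans(D), sxx = colSums(D^2) - nrow(D) * dm^2) {
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  sxy <- as.vector(crossprod(D, yc))
  effect <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- pmax(syy - ifelse(sxx > 0, sxy^2 / sxx, 0), 0)
  se <- ifelse(sxx > 0, sqrt(rss / (n - 2) / sxx), NA_real_)
  chi2 <- ifelse(sxx > 0,
                 ifelse(se > 0, (effect / se)^2,
                        ifelse(effect == 0, 0, Inf)),
                 NA_real_)
  list(effect = effect, se = se, chi2 = chi2)
}

align_residuals <- function(residuals, genotypes) {
  if (inherits(residuals, "residual_set")) {
    y <- residuals$residuals
    if (!is.null(names(y)) && !is.null(genotypes$ids)) {
      bad <- setdiff(genotypes$ids, names(y))
      if (length(bad))
        stop("residual/genotype ID mismatch; missing residuals for: ",
             paste(utils::head(bad, 5), collapse = ", "),
             if (length(bad) > 5) ", ..." else "")
      y <- y[genotypes$ids]
    }
    return(as.numeric(y))
  }
  y <- residuals
  if (!is.null(names(y)) && !is.null(genotypes$ids) &&
      all(genotypes$ids %in% names(y)))
    y <- y[genotypes$ids]
  if (length(y) != nrow(genotypes$doses))
    stop("residual/genotype dimension mismatch")
  as.numeric(y)
}

#' Genome-wide GRAMMAR scan
#'
#' Applies [snp_regression()] to every SNP; records are ordered by
#' (chromosome, position).  If a [permutation_threshold()] null is
#' supplied, permutation-adjusted genome-wide p-values and a significance
#' flag (adjusted p <= alpha) are appended.
#'
#' @param residuals A [grammar_residuals()] result (or a plain vector
#'   aligned with, or named by, the genotype IDs).
#' @param genotypes QC-filtered [genotype_matrix()] object.
#' @param label Scan label (trait or PC name) carried into the output.
#' @param perm_null Optional [permutation_threshold()] result.
#' @return Data frame of class `scan_result`: snp, chr, pos (Mb), effect,
#'   se, chi2, p_nominal, and with a null: p_genomewide, significant.
#' @export
genome_scan <- function(residuals, genotypes, label = "trait",
                        perm_null = NULL) {
  stopifnot(inherits(genotypes, "genotypes"))
  y <- align_residuals(residuals, genotypes)
  D <- genotypes$doses
  storage.mode(D) <- "double"
  st <- scan_stats(y, D)
  out <- data.frame(label = label,
                    snp = genotypes$map$snp,
                    chr = genotypes$map$chr,
                    pos = genotypes$map$pos,
                    effect = st$effect,
                    se = st$se,
                    chi2 = st$chi2,
                    p_nominal = stats::pchisq(st$chi2, df = 1,
                                              lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chr, out$pos), ]
  rownames(out) <- NULL
  if (!is.null(perm_null)) {
    stopifnot(inherits(perm_null, "perm_null"))
    out$p_genomewide <- vapply(out$chi2, function(s) {
      if (is.na(s)) return(NA_real_)
      perm_pvalue(perm_null, s)
    }, numeric(1))
    out$significant <- !is.na(out$p_genomewide) &
      out$p_genomewide <= perm_null$alpha
  }
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation null distribution for genome-wide significance
#'
#' Permutes the residuals across individuals (genotypes fixed, preserving
#' LD and marker structure), reruns the full scan each time, and records
#' the genome-wide maximum chi-square.  The genome-wide adjusted p-value of
#' an observed statistic s is `(1 + #{perm max >= s}) / (B + 1)`; the
#' reported threshold is the statistic above which the adjusted p-value is
#' at most alpha.
#'
#' @param residuals Residual vector or [grammar_residuals()] result.
#' @param genotypes QC-filtered [genotype_matrix()] object.
#' @param B Number of permutations (default 1000).
#' @param alpha Genome-wide significance level (default 0.05); `B * alpha`
#'   must be at least 1.
#' @param seed Integer seed for the permutation stream.
#' @param perms Optional integer matrix (B x n) of explicit permutations,
#'   e.g. an exhaustive enumeration on a tiny sample; overrides `seed`.
#' @return Object of class `perm_null`: `B`, `max_chi2` (B-vector),
#'   `alpha`, `threshold`.
#' @export
permutation_threshold <- function(residuals, genotypes, B = 1000,
                                  alpha = 0.05, seed = NULL, perms = NULL) {
  stopifnot(inherits(genotypes, "genotypes"), alpha > 0, alpha < 1)
  y <- align_residuals(residuals, genotypes)
  n <- length(y)
  if (!is.null(perms)) {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == n)
    B <- nrow(perms)
  }
  if (B * alpha < 1)
    stop("permutation_threshold: B * alpha < 1, threshold undefined")
  if (B < 20) stop("permutation_threshold: B must be at least 20")
  D <- genotypes$doses
  storage.mode(D) <- "double"
  dm <- colMeans(D)
  sxx <- colSums(D^2) - n * dm^2
  poly <- sxx > 0
  one_max <- function(yp) {
    st <- scan_stats(yp, D, dm, sxx)
    max(st$chi2[poly], na.rm = TRUE)
  }
  max_chi2 <- if (!is.null(perms)) {
    apply(perms, 1, function(ix) one_max(y[ix]))
  } else {
    if (is.null(seed)) stop("permutation_threshold: provide seed or perms")
    with_seed(seed, vapply(seq_len(B), function(b) one_max(sample(y)),
                           numeric(1)))
  }
  k <- floor(alpha * (B + 1))
  threshold <- sort(max_chi2, decreasing = TRUE)[max(k, 1)]
  structure(list(B = B, max_chi2 = max_chi2, alpha = alpha,
                 threshold = threshold),
            class = "perm_null")
}

#' Genome-wide adjusted p-value from a permutation null
#'
#' @param null A [permutation_threshold()] result.
#' @param stat Observed chi-square statistic(s).
#' @return `(1 + #{perm max >= stat}) / (B + 1)` for each statistic.
#' @export
perm_pvalue <- function(null, stat) {
  stopifnot(inherits(null, "perm_null"))
  vapply(stat, function(s) (1 + sum(null$max_chi2 >= s)) / (null$B + 1),
         numeric(1))
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "perm_null: B = %d, alpha = %.3f, genome-wide chi2 threshold = %.3f\n",
    x$B, x$alpha, x$threshold))
  invisible(x)
}

#' Clump significant SNPs into QTL regions
#'
#' Single-linkage chaining per scan label and chromosome: two significant
#' SNPs belong to one region when their distance is at most
#' `merge_distance` Mb (default 10), so a region may extend beyond
#' `merge_distance` through a chain.  The reported interval is the member
#' span widened by `merge_distance/2` on each side, clipped to the
#' chromosome if its length is supplied.
#'
#' @param significant Data frame with columns `chr` and `pos` (Mb);
#'   optional `label` (scan identity; regions are formed per label) and
#'   `chi2` (used to identify the peak SNP).
#' @param merge_distance Chaining distance in Mb (default 10).
#' @param chromosome_length Optional chromosome length in Mb for clipping.
#' @return Data frame of regions: label, chr, start, end (widened
#'   interval), span_start, span_end (member SNP span), n_snps, peak_pos,
#'   peak_stat.  Empty input gives an empty data frame.
#' @export
clump_qtl <- function(significant, merge_distance = 10,
                      chromosome_length = NULL) {
  stopifnot(merge_distance > 0)
  empty <- data.frame(label = character(), chr = integer(),
                      start = numeric(), end = numeric(),
                      span_start = numeric(), span_end = numeric(),
                      n_snps = integer(), peak_pos = numeric(),
                      peak_stat = numeric(), stringsAsFactors = FALSE)
  if (is.null(significant) || nrow(significant) == 0) return(empty)
  stopifnot(all(c("chr", "pos") %in% names(significant)))
  df <- as.data.frame(significant)
  if (is.null(df$label)) df$label <- "scan"
  if (is.null(df$chi2)) df$chi2 <- NA_real_
  out <- empty
  for (lab in unique(df$label)) {
    for (cc in sort(unique(df$chr[df$label == lab]))) {
      sub <- df[df$label == lab & df$chr == cc, ]
      sub <- sub[order(sub$pos), ]
      gaps <- diff(sub$pos)
      grp <- cumsum(c(1, as.integer(gaps > merge_distance + POS_TOL)))
      for (g in unique(grp)) {
        mem <- sub[grp == g, ]
        start <- min(mem$pos) - merge_distance / 2
        end <- max(mem$pos) + merge_distance / 2
        start <- max(start, 0)
        if (!is.null(chromosome_length)) end <- min(end, chromosome_length)
        pk <- if (all(is.na(mem$chi2))) which.min(mem$pos)
              else which.max(mem$chi2)
        out <- rbind(out, data.frame(
          label = lab, chr = cc, start = start, end = end,
          span_start = min(mem$pos), span_end = max(mem$pos),
          n_snps = nrow(mem), peak_pos = mem$pos[pk],
          peak_stat = mem$chi2[pk], stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
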