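#' Reference-allele frequency from allele doses
#'
#' @param doses Vector of allele doses in 0/1/2 (NA allowed; frequency uses
#'   non-missing entries).
#' @return Frequency of the counted (reference) allele, `mean(dose)/2`.
#'   The major-allele frequency used by the kinship formula is
#'   `max(p, 1 - p)`.
#' @examples
#' allele_frequency(c(0, 1, 2, 2)) # 0.625
#' @export
allele_frequency <- function(doses) {
  doses <- doses[!is.na(doses)]
  if (!length(doses)) stop("allele_frequency: no non-missing doses")
  mean(doses) / 2
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Pearson chi-square of observed genotype counts against the
#' Hardy-Weinberg expectation at the sample allele frequency.  Monomorphic
#' SNPs return `(0, 1)`: they carry no HWE information and are left to the
#' MAF rule.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts
#'   (AA = two reference alleles).
#' @return List with `chi2` and `p`.
#' @examples
#' hwe_test(c(25, 50, 25)) # chi2 = 0, p = 1
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3)
  if (any(counts < 0)) stop("hwe_test: negative counts")
  n <- sum(counts)
  if (n == 0) stop("hwe_test: empty sample")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Marker quality control: MAF and Hardy-Weinberg filters
#'
#' Removes every SNP with minor allele frequency below `maf_threshold` or a
#' Hardy-Weinberg 1-df chi-square p-value below `hwe_alpha` (the classical
#' pre-association filters).  A SNP failing both rules is attributed to the
#' MAF rule in the report (first-rule-wins accounting).  Frequencies use
#' non-missing doses only.
#'
#' @param genotypes A [genotype_matrix()] object.
#' @param maf_threshold Minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 0.01).
#' @return List with `genotypes` (filtered, SNP order preserved) and
#'   `report` (class `qc_report`): totals plus a per-SNP table of MAF, HWE
#'   chi-square/p and retention flag.
#' @export
apply_qc <- function(genotypes, maf_threshold = 0.01, hwe_alpha = 0.01) {
  stopifnot(inherits(genotypes, "genotypes"),
            maf_threshold >= 0, maf_threshold < 1,
            hwe_alpha >= 0, hwe_alpha < 1)
  D <- genotypes$doses
  m <- ncol(D)
  maf <- numeric(m); hchi <- numeric(m); hp <- numeric(m)
  for (k in seq_len(m)) {
    d <- D[, k]; d <- d[!is.na(d)]
    p <- mean(d) / 2
    maf[k] <- min(p, 1 - p)
    h <- hwe_test(c(sum(d == 2), sum(d == 1), sum(d == 0)))
    hchi[k] <- h$chi2; hp[k] <- h$p
  }
  fail_maf <- maf < maf_threshold
  fail_hwe <- hp < hwe_alpha
  retained <- !(fail_maf | fail_hwe)
  if (!any(retained))
    stop("apply_qc: all SNPs removed; downstream association is impossible")
  per_snp <- data.frame(snp = genotypes$map$snp,
                        chr = genotypes$map$chr,
                        pos = genotypes$map$pos,
                        maf = maf, hwe_chi2 = hchi, hwe_p = hp,
                        retained = retained,
                        rule = ifelse(retained, "",
                                      ifelse(fail_maf, "maf", "hwe")),
                        stringsAsFactors = FALSE)
  report <- structure(list(
    n_input_snps = m,
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe & !fail_maf),
    n_retained = sum(retained),
    maf_threshold = maf_threshold,
    hwe_alpha = hwe_alpha,
    hwe_test = "pearson_chi2_1df",
    per_snp = per_snp
  ), class = "qc_report")
  filtered <- genotype_matrix(D[, retained, drop = FALSE],
                              genotypes$map[retained, , drop = FALSE],
                              ids = genotypes$ids)
  list(genotypes = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d SNPs in, %d removed (MAF < %g: %d; HWE p < %g: %d), %d retained\n",
    x$n_input_snps, x$n_input_snps - x$n_retained,
    x$maf_threshold, x$n_removed_maf, x$hwe_alpha, x$n_removed_hwe,
    x$n_retained))
  invisible(x)
}
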