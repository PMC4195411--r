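#' Significant SNPs reported for the QTL-MAS 2012 dataset
#'
#' The genome-wide significant SNP coordinates (with per-dose effects and
#' chi-square statistics) from the original GRAMMAR analyses of the
#' QTL-MAS 2012 workshop dataset, for the three traits and the two trait
#' principal components.  Shipped as a worked example for [clump_qtl()]:
#' chaining the trait-level hits at 10 Mb yields ten QTL regions on four
#' chromosomes.
#'
#' @return Data frame with columns label, chr, pos (Mb), effect, se, chi2.
#' @export
reported_grammar_hits <- function() {
  path <- system.file("extdata", "qtlmas2012_grammar_hits.tsv",
                      package = "pleioscan", mustWork = TRUE)
  read_tsv_plain(path)
}

#' SNPs reported by the multivariate Bayesian analysis of QTL-MAS 2012
#'
#' log10 Bayes factors of the loci flagged by the original conjugate
#' multivariate analysis of the same dataset; a worked example for
#' [classify_bf()].
#'
#' @return Data frame with columns chr, pos (Mb), log10_bf.
#' @export
reported_bayes_hits <- function() {
  path <- system.file("extdata", "qtlmas2012_bayes_hits.tsv",
                      package = "pleioscan", mustWork = TRUE)
  read_tsv_plain(path)
}
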