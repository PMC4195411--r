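#' Genomic relationship (kinship) matrix
#'
#' Estimates pairwise genomic kinship as the SNP-averaged standardized
#' allele-sharing
#' \deqn{G_{ij} = \frac{1}{n}\sum_k \frac{(g_{ik}-p_k)(g_{jk}-p_k)}{p_k(1-p_k)}}
#' with the genotype on the allelic scale \eqn{g \in \{0, 0.5, 1\}} (half
#' the allele count) and \eqn{p_k} the sample allele frequency.  On this
#' scale G estimates the kinship-coefficient matrix: expected diagonal
#' about 0.5 and full sibs about 0.25; the REML fitters rescale it
#' internally (see [kinship_eigen()]).  The products are invariant to which
#' allele is labelled reference, so major/minor relabelling leaves G
#' unchanged.
#'
#' With `coding = "vanraden"` the familiar 0/1/2 coding with denominator
#' \eqn{2p_k(1-p_k)} is used instead, which is exactly twice the allelic
#'-scale matrix (diagonal about 1, full sibs about 0.5).
#'
#' Monomorphic SNPs carry no information and are skipped (with a warning
#' naming the count); the averaging uses the number of SNPs retained.
#' Missing doses are mean-imputed per SNP (logged via a message).
#'
#' @param genotypes A [genotype_matrix()] object with at least two
#'   polymorphic SNPs.
#' @param coding `"allelic"` (default, 0/0.5/1 over p(1-p)) or
#'   `"vanraden"` (0/1/2 over 2p(1-p)).
#' @return An object of class `kinship`: list with the symmetric matrix
#'   `values`, `ids`, and `n_snps_used`.
#' @export
compute_kinship <- function(genotypes, coding = c("allelic", "vanraden")) {
  coding <- match.arg(coding)
  stopifnot(inherits(genotypes, "genotypes"))
  D <- genotypes$doses
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    message("compute_kinship: mean-imputing ", sum(is.na(D)), " missing doses")
    mu <- colMeans(D, na.rm = TRUE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  p <- colMeans(D) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("compute_kinship: fewer than 2 polymorphic SNPs")
  if (any(!poly))
    warning(sprintf("compute_kinship: %d monomorphic SNPs skipped",
                    sum(!poly)))
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  # allelic scale: g = dose/2, centered at p, scaled by sqrt(p(1-p));
  # vanraden is the same matrix times 2
  Z <- sweep(D / 2, 2, p, "-")
  Z <- sweep(Z, 2, sqrt(p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  if (coding == "vanraden") G <- 2 * G
  G <- (G + t(G)) / 2
  dimnames(G) <- list(genotypes$ids, genotypes$ids)
  structure(list(values = G, ids = genotypes$ids, n_snps_used = ncol(Z),
                 coding = coding),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship: %d individuals, %d SNPs used (%s coding)\n",
              length(x$ids), x$n_snps_used, x$coding))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              (sum(x$values) - sum(diag(x$values))) /
                (length(x$ids)^2 - length(x$ids))))
  invisible(x)
}

#' Spectral decomposition of the (rescaled) relationship matrix
#'
#' The mixed-model fitters work in the eigenbasis of the relationship
#' matrix so one decomposition is reused across traits, principal
#' components and permutations.  The kinship matrix is first rescaled to
#' mean diagonal 1, putting the additive variance on the phenotypic
#' variance scale regardless of the kinship coding; eigenvalues below a
#' small floor are clipped (near-PSD repair, logged via a warning when the
#' clip is material).
#'
#' @param kinship A [compute_kinship()] result (or a bare symmetric matrix).
#' @param floor Eigenvalue floor (default 1e-8).
#' @return List with orthonormal `vectors`, clipped eigenvalues `values`,
#'   `ids` and the mean-diagonal scale factor applied.
#' @export
kinship_eigen <- function(kinship, floor = 1e-8) {
  A <- if (inherits(kinship, "kinship")) kinship$values else as.matrix(kinship)
  ids <- if (inherits(kinship, "kinship")) kinship$ids else rownames(A)
  scale_factor <- mean(diag(A))
  if (scale_factor <= 0) stop("kinship_eigen: non-positive mean diagonal")
  A <- A / scale_factor
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(ev$values) < -0.05)
    warning(sprintf(
      "kinship_eigen: clipping eigenvalues as low as %.3g to %.1g",
      min(ev$values), floor))
  d <- pmax(ev$values, floor)
  if (stats::sd(d) < 1e-8)
    stop("kinship matrix is proportional to the identity: ",
         "variance components are not identifiable")
  list(vectors = ev$vectors, values = d, ids = ids,
       scale_factor = scale_factor)
}
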