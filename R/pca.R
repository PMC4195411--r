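# Principal components of the phenotypic correlation matrix.  PC scores act
# as additional scan phenotypes: loci that move several correlated traits at
# once load on few components, so scanning the PCs concentrates pleiotropic
# signal.

pheno_values <- function(phenotypes, traits = NULL) {
  stopifnot(is.data.frame(phenotypes), "id" %in% names(phenotypes))
  if (is.null(traits)) {
    num <- vapply(phenotypes, is.numeric, logical(1))
    traits <- setdiff(names(phenotypes)[num], "id")
  }
  missing_tr <- setdiff(traits, names(phenotypes))
  if (length(missing_tr))
    stop("phenotype columns not found: ", paste(missing_tr, collapse = ", "))
  as.matrix(phenotypes[traits])
}

#' Principal components of the trait correlation matrix
#'
#' Eigendecomposition of the sample correlation matrix of the traits
#' (correlation, not covariance: the traits deliberately live on very
#' different scales).  Eigenvector signs are fixed deterministically: each
#' column is flipped so that its largest-magnitude loading is positive.
#' PC-trait correlations are the Pearson correlations between the PC scores
#' and the original traits.
#'
#' @param phenotypes Phenotype data frame (`id` column plus trait columns).
#' @param traits Trait column names (default: all numeric non-id columns).
#' @return Object of class `pc_model`: `eigenvalues` (descending,
#'   summing to the number of traits), `eigenvectors` (orthonormal
#'   columns), `variance_shares`, `pc_trait_correlations`, standardisation
#'   `center`/`scale`, and `retained` (initially all PCs).
#' @export
trait_pca <- function(phenotypes, traits = NULL) {
  Y <- pheno_values(phenotypes, traits)
  if (nrow(Y) < 3) stop("trait_pca: need at least 3 individuals")
  sds <- apply(Y, 2, stats::sd)
  if (any(sds == 0))
    stop("trait_pca: zero-variance trait: ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  R <- stats::cor(Y)
  ev <- eigen(R, symmetric = TRUE)
  vec <- ev$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  q <- ncol(Y)
  scores <- scale(Y) %*% vec
  ptc <- stats::cor(scores, Y)
  pcn <- paste0("pc", seq_len(q))
  dimnames(vec) <- list(colnames(Y), pcn)
  dimnames(ptc) <- list(pcn, colnames(Y))
  structure(list(eigenvalues = ev$values,
                 eigenvectors = vec,
                 variance_shares = ev$values / q,
                 pc_trait_correlations = ptc,
                 center = colMeans(Y),
                 scale = sds,
                 traits = colnames(Y),
                 correlation = R,
                 retained = seq_len(q)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model on traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  variance shares:",
      paste(sprintf("%.1f%%", 100 * x$variance_shares), collapse = ", "), "\n")
  cat("  retained:", paste0("pc", x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Append principal-component scores as new phenotypes
#'
#' Scores are the z-scored traits (using the centering/scaling stored in
#' the model) projected on the eigenvectors; only retained PCs (see
#' [select_pcs()]) are appended.  Score columns are named `pc1`, `pc2`, ...
#'
#' @param phenotypes Phenotype data frame containing the model's traits.
#' @param model A [trait_pca()] result.
#' @return The phenotype data frame with PC score columns appended.
#' @export
pc_scores <- function(phenotypes, model) {
  stopifnot(inherits(model, "pc_model"))
  if (!all(model$traits %in% names(phenotypes)))
    stop("pc_scores: phenotype table lacks trait(s): ",
         paste(setdiff(model$traits, names(phenotypes)), collapse = ", "))
  Y <- as.matrix(phenotypes[model$traits])
  Z <- sweep(sweep(Y, 2, model$center, "-"), 2, model$scale, "/")
  S <- Z %*% model$eigenvectors
  keep <- model$retained
  out <- phenotypes
  for (j in keep) out[[paste0("pc", j)]] <- S[, j]
  out
}

#' Retain principal components by explained-variance share
#'
#' Drops components explaining less than `min_share` of total variance
#' (default 1%), mirroring the practice of excluding a trailing PC with
#' negligible variance from downstream scans.
#'
#' @param model A [trait_pca()] result.
#' @param min_share Minimum variance share to keep a PC (in (0, 1);
#'   0 retains all).
#' @return The model with an updated `retained` index vector.
#' @export
select_pcs <- function(model, min_share = 0.01) {
  stopifnot(inherits(model, "pc_model"), min_share >= 0, min_share < 1)
  model$retained <- which(model$variance_shares >= min_share)
  model
}
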