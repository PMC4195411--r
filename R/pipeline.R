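#' Run the full multi-trait association pipeline
#'
#' End-to-end driver: marker QC, genomic kinship, univariate REML and
#' GRAMMAR residuals for each trait, trait PCA with PC-score scan
#' phenotypes, permutation-corrected GRAMMAR scans for every trait and
#' retained PC, QTL clumping, the multivariate Bayes-factor scan, and
#' bivariate REML refits of each trait pair with the identified SNPs as
#' fixed covariates.  Every intermediate table is written to `out_dir` as
#' a headered TSV (positions in Mb, dose = reference-allele count, Bayes
#' factors on log10), together with a structured log recording the seed,
#' package version and per-stage counts.  All randomness flows from the
#' single `seed` through named substreams, so reruns are byte-identical.
#'
#' @param genotypes A [genotype_matrix()] object (pre-QC).
#' @param phenotypes Phenotype data frame (`id` column + trait columns)
#'   whose row order matches the genotype individuals.
#' @param out_dir Output directory (created if needed).
#' @param traits Trait column names (default: all numeric non-id columns).
#' @param maf_threshold,hwe_alpha QC thresholds (defaults 0.01, 0.01).
#' @param n_permutations,alpha Permutation count and genome-wide level per
#'   scan (defaults 1000, 0.05).
#' @param pc_min_share Minimum variance share for a PC to be scanned
#'   (default 0.01).
#' @param prior [prior_spec()] for the multivariate scan.
#' @param bf_suggestive,bf_significant log10 Bayes-factor thresholds.
#' @param merge_distance QTL clumping distance in Mb (default 10).
#' @param chromosome_length Optional chromosome length (Mb) for clipping
#'   region intervals.
#' @param seed Master seed (mandatory).
#' @param write_kinship Also write the full kinship matrix TSV (off by
#'   default: n x n).
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with every intermediate object (qc, kinship,
#'   varcomp, residuals, pca, scans, nulls, qtl regions, Bayes scan,
#'   refits, file paths).
#' @export
run_pipeline <- function(genotypes, phenotypes, out_dir,
                         traits = NULL,
                         maf_threshold = 0.01, hwe_alpha = 0.01,
                         n_permutations = 1000, alpha = 0.05,
                         pc_min_share = 0.01,
                         prior = prior_spec(),
                         bf_suggestive = 3, bf_significant = 5,
                         merge_distance = 10,
                         chromosome_length = NULL,
                         seed,
                         write_kinship = FALSE,
                         verbose = TRUE) {
  if (missing(seed)) stop("run_pipeline: a master seed is mandatory")
  stopifnot(inherits(genotypes, "genotypes"), is.data.frame(phenotypes))
  if (!identical(as.character(phenotypes$id), as.character(genotypes$ids)))
    stop("run_pipeline: phenotype IDs do not match genotype IDs ",
         "(same individuals in the same order are required)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("pleioscan %s", as.character(utils::packageVersion("pleioscan"))),
    sprintf("seed\t%d", as.integer(seed)),
    sprintf("individuals\t%d", nrow(genotypes$doses)))
  path_of <- function(name) file.path(out_dir, name)
  if (is.null(traits)) {
    num <- vapply(phenotypes, is.numeric, logical(1))
    traits <- setdiff(names(phenotypes)[num], "id")
  }

  # -- QC ---------------------------------------------------------------
  msg(verbose, "QC: filtering %d SNPs", ncol(genotypes$doses))
  qc <- apply_qc(genotypes, maf_threshold, hwe_alpha)
  geno <- qc$genotypes
  rep_ <- qc$report
  log_lines <- c(log_lines,
    sprintf("qc_input\t%d", rep_$n_input_snps),
    sprintf("qc_removed_maf\t%d", rep_$n_removed_maf),
    sprintf("qc_removed_hwe\t%d", rep_$n_removed_hwe),
    sprintf("qc_retained\t%d", rep_$n_retained),
    sprintf("qc_identity\t%d = %d + %d",
            rep_$n_input_snps, rep_$n_retained,
            rep_$n_input_snps - rep_$n_retained))
  write_tsv_commented(rep_$per_snp, path_of("qc_report.tsv"),
    c("per-SNP quality control; positions in Mb",
      sprintf("removed iff maf < %g or hwe_p < %g (1-df Pearson chi-square)",
              maf_threshold, hwe_alpha)))

  # -- kinship ----------------------------------------------------------
  msg(verbose, "kinship: %d individuals x %d SNPs",
      nrow(geno$doses), ncol(geno$doses))
  kin <- compute_kinship(geno)
  eig <- kinship_eigen(kin)
  if (write_kinship) {
    km <- data.frame(id = kin$ids, kin$values, check.names = FALSE)
    write_tsv_commented(km, path_of("kinship.tsv"),
      c("genomic kinship matrix, allelic-scale standardized allele sharing"))
  }

  # -- univariate REML + GRAMMAR residuals for the raw traits -----------
  vcs <- list(); residuals <- list()
  for (tr in traits) {
    msg(verbose, "REML: %s", tr)
    vcs[[tr]] <- fit_univariate_reml(phenotypes[[tr]], eig = eig)
    residuals[[tr]] <- grammar_residuals(phenotypes[[tr]], vc = vcs[[tr]],
                                         eig = eig)
  }
  varcomp_tbl <- data.frame(
    trait = traits,
    h2 = vapply(vcs, function(v) v$h2, numeric(1)),
    se_h2 = vapply(vcs, function(v) v$se_h2, numeric(1)),
    sigma2_a = vapply(vcs, function(v) v$sigma2_a, numeric(1)),
    sigma2_e = vapply(vcs, function(v) v$sigma2_e, numeric(1)),
    loglik = vapply(vcs, function(v) v$loglik, numeric(1)),
    row.names = NULL)
  write_tsv_commented(varcomp_tbl, path_of("varcomp.tsv"),
    "univariate REML variance components per trait")

  # -- bivariate REML: genetic/phenotypic correlations ------------------
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  base_biv <- list()
  corr_tbl <- do.call(rbind, lapply(pairs, function(pr) {
    msg(verbose, "bivariate REML: %s / %s", pr[1], pr[2])
    f <- fit_bivariate_reml(phenotypes[[pr[1]]], phenotypes[[pr[2]]],
                            eig = eig)
    base_biv[[paste(pr, collapse = "/")]] <<- f
    data.frame(trait_a = pr[1], trait_b = pr[2],
               r_g = f$r_g, se_rg = f$se_rg, r_p = f$r_p)
  }))
  write_tsv_commented(corr_tbl, path_of("correlations.tsv"),
    "bivariate REML genetic (r_g) and phenotypic (r_p) correlations")

  # -- PCA --------------------------------------------------------------
  pca <- select_pcs(trait_pca(phenotypes, traits), pc_min_share)
  pc_tbl <- data.frame(
    pc = paste0("pc", seq_along(pca$eigenvalues)),
    eigenvalue = pca$eigenvalues,
    variance_share = pca$variance_shares,
    retained = seq_along(pca$eigenvalues) %in% pca$retained)
  pc_tbl <- cbind(pc_tbl, as.data.frame(pca$pc_trait_correlations))
  write_tsv_commented(pc_tbl, path_of("pca.tsv"),
    c("principal components of the trait correlation matrix",
      "trait columns give PC-score/trait Pearson correlations"))
  pheno_pc <- pc_scores(phenotypes, pca)
  write_phenotypes(pheno_pc, path_of("phenotypes_pc.tsv"))
  pc_labels <- paste0("pc", pca$retained)
  log_lines <- c(log_lines,
    sprintf("pcs_retained\t%s", paste(pc_labels, collapse = ",")))

  # -- REML + residuals for retained PC scores --------------------------
  for (pc in pc_labels) {
    msg(verbose, "REML: %s", pc)
    vcs[[pc]] <- fit_univariate_reml(pheno_pc[[pc]], eig = eig)
    residuals[[pc]] <- grammar_residuals(pheno_pc[[pc]], vc = vcs[[pc]],
                                         eig = eig)
  }
  resid_tbl <- data.frame(id = geno$ids,
                          lapply(residuals, function(r) r$residuals),
                          check.names = FALSE)
  write_tsv_commented(resid_tbl, path_of("residuals.tsv"),
    "GRAMMAR residuals y* = y - (mu + blup) per scan phenotype")

  # -- GRAMMAR scans with per-scan permutation nulls --------------------
  labels <- c(traits, pc_labels)
  scans <- list(); nulls <- list()
  for (lab in labels) {
    msg(verbose, "scan: %s (%d permutations)", lab, n_permutations)
    nulls[[lab]] <- permutation_threshold(
      residuals[[lab]], geno, B = n_permutations, alpha = alpha,
      seed = substream_seed(seed, paste0("perm_", lab)))
    scans[[lab]] <- genome_scan(residuals[[lab]], geno, label = lab,
                                perm_null = nulls[[lab]])
  }
  scan_tbl <- do.call(rbind, scans)
  rownames(scan_tbl) <- NULL
  write_tsv_commented(scan_tbl, path_of("scan.tsv"),
    c("GRAMMAR association scan; positions in Mb; chi2 is 1-df",
      sprintf("p_genomewide from %d residual permutations per scan",
              n_permutations)))
  null_tbl <- data.frame(label = labels,
                         B = vapply(nulls, function(x) x$B, numeric(1)),
                         alpha = alpha,
                         chi2_threshold = vapply(nulls, function(x)
                           x$threshold, numeric(1)), row.names = NULL)
  write_tsv_commented(null_tbl, path_of("null.tsv"),
    "per-scan permutation genome-wide chi2 thresholds")
  manhattan <- scan_tbl[c("label", "chr", "pos")]
  manhattan$neglog10_p <- -log10(pmax(scan_tbl$p_nominal, 1e-300))
  write_tsv_commented(manhattan, path_of("manhattan.tsv"),
    "plot-ready nominal -log10 p per SNP and scan")

  # -- clump significant SNPs into QTL regions --------------------------
  sig <- scan_tbl[!is.na(scan_tbl$significant) & scan_tbl$significant, ]
  qtl <- clump_qtl(sig, merge_distance = merge_distance,
                   chromosome_length = chromosome_length)
  write_tsv_commented(qtl, path_of("qtl.tsv"),
    sprintf("QTL regions: single-linkage chaining of significant SNPs at <= %g Mb",
            merge_distance))
  log_lines <- c(log_lines,
    sprintf("significant_snps\t%d", nrow(sig)),
    sprintf("qtl_regions\t%d", nrow(qtl)))

  # -- multivariate Bayes-factor scan -----------------------------------
  msg(verbose, "multivariate Bayes-factor scan")
  bf <- mv_scan(residuals[traits], geno, prior = prior,
                suggestive = bf_suggestive, significant = bf_significant)
  write_tsv_commented(bf, path_of("bf.tsv"),
    c("multivariate conjugate Bayes-factor scan over all traits (log10 scale)",
      sprintf("class thresholds: suggestive >= %g, significant >= %g",
              bf_suggestive, bf_significant)))

  # -- refits: trait-pair r_g with identified SNPs as fixed effects -----
  hit_sets <- list()
  for (lab in labels) {
    hits <- sig$snp[sig$label == lab]
    if (length(hits)) hit_sets[[lab]] <- hits
  }
  bf_hits <- bf$snp[!is.na(bf$class) & bf$class != "none"]
  if (length(bf_hits)) hit_sets[["bayes_mv"]] <- bf_hits
  refits <- list()
  refit_tbl <- do.call(rbind, lapply(c("none", names(hit_sets)), function(lab) {
    do.call(rbind, lapply(pairs, function(pr) {
      if (lab == "none") {
        f <- base_biv[[paste(pr, collapse = "/")]]
      } else {
        snps <- hit_sets[[lab]]
        msg(verbose, "refit r_g(%s, %s) with %d SNP(s) from %s",
            pr[1], pr[2], length(snps), lab)
        f <- refit_with_snp_covariates(
          phenotypes[[pr[1]]], phenotypes[[pr[2]]],
          snp_doses = geno$doses[, snps, drop = FALSE], eig = eig)
        refits[[paste(lab, pr[1], pr[2], sep = "/")]] <<- f
      }
      data.frame(snp_set = lab, trait_a = pr[1], trait_b = pr[2],
                 n_snps = if (lab == "none") 0L else length(hit_sets[[lab]]),
                 r_g = f$r_g, r_p = f$r_p)
    }))
  }))
  write_tsv_commented(refit_tbl, path_of("rg_refit.tsv"),
    c("genetic correlations with identified SNPs fitted as fixed effects",
      "snp_set 'none' is the base animal model without SNP covariates"))

  writeLines(log_lines, path_of("pipeline.log"))
  msg(verbose, "pipeline complete: outputs in %s", out_dir)
  invisible(list(qc = qc, kinship = kin, eigen = eig, varcomp = vcs,
                 correlations = corr_tbl, residuals = residuals, pca = pca,
                 phenotypes_pc = pheno_pc, scans = scans, nulls = nulls,
                 scan_table = scan_tbl, qtl = qtl, bayes = bf,
                 refit_table = refit_tbl, out_dir = out_dir))
}
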