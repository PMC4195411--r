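#' Specify a simulated QTL
#'
#' A QTL is placed at a map position on one chromosome and assigns an
#' additive effect, in phenotypic-standard-deviation units per allele copy,
#' to each of the three traits.  A zero entry means the locus does not
#' affect that trait; at least one entry must be nonzero.
#'
#' @param chromosome Chromosome index (1-based).
#' @param position Position in Mb.  The effect is attached to the simulated
#'   SNP nearest this position.
#' @param effects Numeric vector of length 3: per-allele effect on each
#'   trait in phenotypic-SD units.
#' @return An object of class `qtl_spec`.
#' @seealso [default_qtl_panel()], [sim_config()]
#' @export
qtl_spec <- function(chromosome, position, effects) {
  stopifnot(length(chromosome) == 1, length(position) == 1,
            is.numeric(effects), length(effects) == 3)
  if (all(effects == 0))
    stop("a QTL must have a nonzero effect on at least one trait")
  structure(list(chromosome = as.integer(chromosome),
                 position = as.numeric(position),
                 effects = as.numeric(effects)),
            class = "qtl_spec")
}

#' Default QTL panel emulating the QTL-MAS 2012 architecture
#'
#' Seven pleiotropic and trait-specific QTL on chromosomes 1-4 (chromosome 5
#' deliberately empty), at the map positions where the original workshop
#' analyses localised large-effect loci.  Effect sizes are set so that each
#' locus explains roughly 0.5-2% of phenotypic variance, the order of
#' magnitude implied by the chi-square statistics reported for that dataset,
#' with signs chosen to be consistent with the trait correlation structure
#' (traits 1 and 2 positively coupled, traits 1 and 3 negatively).
#'
#' @return A list of [qtl_spec()] objects.
#' @export
default_qtl_panel <- function() {
  list(
    qtl_spec(1, 14.60, c(0.00, 0.20, 0.00)),
    qtl_spec(1, 58.00, c(0.00, 0.00, 0.14)),
    qtl_spec(1, 84.05, c(0.16, 0.00, -0.22)),
    qtl_spec(2, 79.15, c(0.00, 0.00, 0.19)),
    qtl_spec(3, 2.15, c(0.00, -0.14, -0.14)),
    qtl_spec(3, 36.85, c(0.00, 0.00, 0.13)),
    qtl_spec(4, 24.90, c(0.24, 0.27, 0.00))
  )
}

default_genetic_correlations <- function() {
  m <- matrix(c(1, 0.84, -0.43,
                0.84, 1, 0.11,
                -0.43, 0.11, 1), 3, 3)
  m
}

default_phenotypic_correlations <- function() {
  m <- matrix(c(1, 0.82, -0.44,
                0.82, 1, 0.14,
                -0.44, 0.14, 1), 3, 3)
  m
}

check_corr_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != 3 || ncol(m) != 3)
    stop(what, " must be a 3x3 matrix")
  if (max(abs(m - t(m))) > 1e-8) stop(what, " must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop(what, " must have unit diagonal")
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop(what, " must be positive semi-definite")
  invisible(m)
}

#' Configuration for the synthetic genotype/phenotype generator
#'
#' Defines the study conditions the generator emulates: five chromosomes of
#' equally spaced biallelic SNPs, a related population bred from a small
#' founder haplotype pool by random mating, and three quantitative traits
#' with the heritabilities and genetic/phenotypic correlations of the
#' QTL-MAS 2012 workshop traits, plus a panel of large pleiotropic QTL.
#'
#' @param n_individuals Number of individuals in the final generation.
#' @param n_chromosomes Number of chromosomes (default 5).
#' @param snps_per_chromosome SNPs per chromosome, equally spaced.
#' @param chromosome_length Chromosome length in Mb (default 100).
#' @param n_founder_haplotypes Size of the founder haplotype pool.  Base-
#'   generation haplotypes are mosaics of this pool (see
#'   `mosaic_segment_mb`); smaller pools give stronger linkage
#'   disequilibrium and background relatedness, while a pool of
#'   `2 * n_individuals` with `n_generations = 0` yields effectively
#'   unrelated individuals.
#' @param n_generations Generations of random mating after the founders
#'   (default 3); relatedness and recent LD accumulate here.
#' @param heritabilities Length-3 vector of narrow-sense heritabilities,
#'   strictly inside (0, 1).  Defaults to the workshop values
#'   (0.56, 0.55, 0.66).
#' @param genetic_correlations 3x3 genetic correlation matrix (default:
#'   off-diagonals 0.84, -0.43, 0.11).
#' @param phenotypic_correlations 3x3 phenotypic correlation matrix
#'   (default: off-diagonals 0.82, -0.44, 0.14).  Residual covariances are
#'   derived as the gap between phenotypic and total genetic covariance.
#' @param qtl_list List of [qtl_spec()] objects; default [default_qtl_panel()].
#'   Use `list()` for a genome with no major loci (null simulations).
#' @param founder_freq_range Range the founder-pool reference-allele
#'   frequencies are drawn from, uniform (default c(0.05, 0.95) so the MAF
#'   filter removes only drifted markers; narrow it towards 0 to emulate
#'   rare variants).
#' @param trait_means,trait_sds Affine output scale per trait.  Defaults give
#'   the traits deliberately different orders of magnitude, as in the
#'   original data where per-allele effects differed by a factor ~1000.
#' @param trait_names Column names for the phenotype table.
#' @param cm_per_mb Map density used for meiosis, centimorgan per Mb
#'   (default 1, i.e. a 100-Mb chromosome is one Morgan).
#' @param mosaic_segment_mb Mean founder-mosaic segment length in Mb for
#'   the base generation (default 5); sets the scale on which linkage
#'   disequilibrium decays.
#' @param seed Mandatory integer seed; the generator is fully deterministic
#'   given the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 3000,
                       n_chromosomes = 5,
                       snps_per_chromosome = 2000,
                       chromosome_length = 100,
                       n_founder_haplotypes = 80,
                       n_generations = 3,
                       heritabilities = c(0.56, 0.55, 0.66),
                       genetic_correlations = default_genetic_correlations(),
                       phenotypic_correlations = default_phenotypic_correlations(),
                       qtl_list = default_qtl_panel(),
                       founder_freq_range = c(0.05, 0.95),
                       trait_means = c(250, 15, 0.30),
                       trait_sds = c(90, 5, 0.012),
                       trait_names = c("trait1", "trait2", "trait3"),
                       cm_per_mb = 1,
                       mosaic_segment_mb = 5,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (snps_per_chromosome < 2) stop("invalid config: snps_per_chromosome < 2")
  if (n_founder_haplotypes < 2) stop("invalid config: n_founder_haplotypes < 2")
  if (n_individuals < 2) stop("invalid config: n_individuals < 2")
  if (n_generations < 0) stop("invalid config: n_generations < 0")
  stopifnot(length(heritabilities) == 3)
  if (any(heritabilities <= 0) || any(heritabilities >= 1))
    stop("invalid config: heritabilities must lie strictly inside (0, 1)")
  check_corr_matrix(genetic_correlations, "genetic_correlations")
  check_corr_matrix(phenotypic_correlations, "phenotypic_correlations")
  for (q in qtl_list) {
    if (!inherits(q, "qtl_spec")) stop("qtl_list entries must be qtl_spec objects")
    if (q$chromosome < 1 || q$chromosome > n_chromosomes)
      stop("invalid config: QTL chromosome out of range")
    if (q$position <= 0 || q$position > chromosome_length)
      stop("invalid config: QTL position outside chromosome bounds")
  }
  stopifnot(length(founder_freq_range) == 2,
            founder_freq_range[1] > 0, founder_freq_range[2] < 1,
            founder_freq_range[1] <= founder_freq_range[2])
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_chromosomes = as.integer(n_chromosomes),
    snps_per_chromosome = as.integer(snps_per_chromosome),
    chromosome_length = as.numeric(chromosome_length),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    n_generations = as.integer(n_generations),
    heritabilities = as.numeric(heritabilities),
    genetic_correlations = genetic_correlations,
    phenotypic_correlations = phenotypic_correlations,
    qtl_list = qtl_list,
    founder_freq_range = as.numeric(founder_freq_range),
    trait_means = as.numeric(trait_means),
    trait_sds = as.numeric(trait_sds),
    trait_names = trait_names,
    cm_per_mb = as.numeric(cm_per_mb),
    mosaic_segment_mb = as.numeric(mosaic_segment_mb),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d individuals, %d chromosomes x %d SNPs (%g Mb each)\n",
    x$n_individuals, x$n_chromosomes, x$snps_per_chromosome,
    x$chromosome_length))
  cat(sprintf("  founder pool %d haplotypes, %d generations of random mating\n",
              x$n_founder_haplotypes, x$n_generations))
  cat(sprintf("  h2 = (%s); %d QTL; seed %d\n",
              paste(x$heritabilities, collapse = ", "),
              length(x$qtl_list), x$seed))
  invisible(x)
}

#' Construct a genotype matrix object
#'
#' Container for an individuals-by-SNPs allele-dose matrix (entries 0/1/2 =
#' copies of the reference allele) with its SNP map (chromosome, position in
#' Mb, allele labels).
#'
#' @param doses Numeric/integer matrix, individuals in rows, SNPs in columns.
#' @param map Data frame with columns `snp`, `chr`, `pos` (Mb), `a1`, `a2`;
#'   `a1` is the counted (reference) allele.
#' @param ids Character vector of individual identifiers.
#' @return An object of class `genotypes`.
#' @export
genotype_matrix <- function(doses, map, ids = rownames(doses)) {
  doses <- as.matrix(doses)
  if (is.null(ids)) ids <- sprintf("ind%05d", seq_len(nrow(doses)))
  stopifnot(nrow(map) == ncol(doses),
            all(c("snp", "chr", "pos") %in% names(map)))
  if (anyDuplicated(ids)) stop("duplicated individual IDs")
  if (anyDuplicated(map$snp)) stop("duplicated SNP identifiers")
  ok <- doses %in% c(0, 1, 2) | is.na(doses)
  if (!all(ok)) stop("doses must be 0, 1, 2 or NA")
  for (cc in unique(map$chr)) {
    p <- map$pos[map$chr == cc]
    if (is.unsorted(p, strictly = TRUE))
      stop("map positions must be strictly increasing within chromosome")
  }
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  rownames(doses) <- ids
  colnames(doses) <- map$snp
  structure(list(doses = doses, map = map, ids = ids), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$doses), ncol(x$doses), length(unique(x$map$chr))))
  if (anyNA(x$doses)) cat(sprintf("  %d missing doses\n", sum(is.na(x$doses))))
  invisible(x)
}

# One base-generation haplotype: a mosaic of founder-pool haplotypes with
# segment switches following a Poisson process along the chromosome.  Local
# LD comes from shared founder segments and decays on the `segment_mb`
# scale, while each mosaic haplotype is globally distinct, so the genotype
# space keeps full rank even for a small founder pool.
mosaic_haplotype <- function(founders, pos, len, segment_mb) {
  nf <- nrow(founders)
  nsw <- stats::rpois(1L, len / segment_mb)
  src <- sample.int(nf, nsw + 1L, replace = TRUE)
  if (nsw == 0L) return(founders[src, ])
  cuts <- sort(stats::runif(nsw, 0, len))
  seg <- findInterval(pos, cuts) + 1L
  founders[cbind(src[seg], seq_along(pos))]
}

# One meiotic product: recombine a parent's two haplotypes with crossover
# positions from a Poisson process at `cm_per_mb`/100 per Mb.
recombine <- function(h1, h2, pos, len, cm_per_mb) {
  ncx <- stats::rpois(1L, len * cm_per_mb / 100)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (ncx == 0L) return(if (start == 1L) h2 else h1)
  cx <- sort(stats::runif(ncx, 0, len))
  seg <- findInterval(pos, cx) + start
  ifelse(seg %% 2L == 0L, h1, h2)
}

#' Simulate genotypes for a related population
#'
#' SNPs are placed on an equal-spacing grid (`chromosome_length /
#' snps_per_chromosome` Mb apart, e.g. the 0.05-Mb grid of the emulated
#' dataset at 2000 SNPs per 100-Mb chromosome).  A founder haplotype pool is
#' drawn with per-SNP reference-allele frequencies uniform on
#' `founder_freq_range`; base-generation haplotypes are segment mosaics of
#' that pool (local LD), and `n_generations` rounds of random mating with
#' recombination (Poisson crossovers at `cm_per_mb`) add family structure
#' and recent LD.  Fully deterministic given `config$seed`.
#'
#' The last-generation pedigree (sire/dam indices per generation) is
#' attached as `attr(, "pedigree")` for relatedness checks.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] object with complete (no missing) doses.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  nf <- config$n_founder_haplotypes
  with_seed(substream_seed(config$seed, "genotypes"), {
    # pedigree drawn once so parent pairs are consistent across chromosomes
    pedigree <- vector("list", config$n_generations)
    if (config$n_generations > 0) {
      for (g in seq_len(config$n_generations)) {
        sire <- sample.int(n, n, replace = TRUE)
        dam <- sample.int(n, n, replace = TRUE)
        while (any(clash <- sire == dam))
          dam[clash] <- sample.int(n, sum(clash), replace = TRUE)
        pedigree[[g]] <- cbind(sire = sire, dam = dam)
      }
    }
    per_chr <- vector("list", config$n_chromosomes)
    maps <- vector("list", config$n_chromosomes)
    for (cc in seq_len(config$n_chromosomes)) {
      m <- config$snps_per_chromosome
      len <- config$chromosome_length
      pos <- seq_len(m) * (len / m)
      p <- stats::runif(m, config$founder_freq_range[1],
                        config$founder_freq_range[2])
      founders <- matrix(stats::rbinom(nf * m, 1L, rep(p, each = nf)),
                         nrow = nf)
      H <- matrix(0L, 2L * n, m)
      for (j in seq_len(2L * n))
        H[j, ] <- mosaic_haplotype(founders, pos, len,
                                   config$mosaic_segment_mb)
      for (g in seq_len(config$n_generations)) {
        ped <- pedigree[[g]]
        Hn <- matrix(0L, 2L * n, m)
        for (j in seq_len(n)) {
          s <- ped[j, 1L]; d <- ped[j, 2L]
          Hn[2L * j - 1L, ] <- recombine(H[2L * s - 1L, ], H[2L * s, ],
                                         pos, len, config$cm_per_mb)
          Hn[2L * j, ] <- recombine(H[2L * d - 1L, ], H[2L * d, ],
                                    pos, len, config$cm_per_mb)
        }
        H <- Hn
      }
      odd <- seq(1L, 2L * n, by = 2L)
      per_chr[[cc]] <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
      maps[[cc]] <- data.frame(
        snp = sprintf("c%ds%04d", cc, seq_len(m)),
        chr = cc, pos = pos, a1 = "A", a2 = "B",
        stringsAsFactors = FALSE)
    }
    geno <- genotype_matrix(do.call(cbind, per_chr), do.call(rbind, maps),
                            ids = sprintf("ind%05d", seq_len(n)))
    attr(geno, "pedigree") <- pedigree
    geno
  })
}

# Map each QTL to the index of the nearest simulated SNP on its chromosome.
qtl_snp_index <- function(genotypes, qtl_list) {
  vapply(qtl_list, function(q) {
    on_chr <- which(genotypes$map$chr == q$chromosome)
    if (!length(on_chr)) stop("QTL chromosome absent from genotype map")
    on_chr[which.min(abs(genotypes$map$pos[on_chr] - q$position))]
  }, integer(1))
}

#' Simulate correlated quantitative traits on a genotyped population
#'
#' Each trait is the sum of (i) fixed additive QTL effects from
#' `config$qtl_list`, (ii) a multivariate polygenic value drawn with
#' between-individual covariance proportional to the realized genomic
#' relationship matrix, and (iii) a multivariate residual.  On the internal
#' standardized scale each trait has unit phenotypic variance; the polygenic
#' covariance is set to the target total genetic covariance (heritabilities
#' on the diagonal, genetic correlations off it) minus the realized QTL
#' covariance, and the residual covariance to the gap between the target
#' phenotypic covariance and the total genetic covariance, so realized
#' heritabilities and genetic/phenotypic correlations match the
#' configuration in expectation.  Output traits are rescaled by
#' `trait_sds`/`trait_means`.
#'
#' The standardized components are attached as `attr(, "components")`
#' (a list with `qtl`, `polygenic`, `residual`, `Sigma_u`, `Sigma_e`).
#'
#' @param genotypes Genotypes from [simulate_genotypes()] under the same
#'   configuration.
#' @param config The [sim_config()] used for the genotypes.
#' @return A phenotype data frame: column `id` plus one column per trait.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotypes"), inherits(config, "sim_config"))
  n <- nrow(genotypes$doses)
  q <- 3L
  h2 <- config$heritabilities
  with_seed(substream_seed(config$seed, "phenotypes"), {
    if (length(config$qtl_list)) {
      idx <- qtl_snp_index(genotypes, config$qtl_list)
      B <- t(vapply(config$qtl_list, function(x) x$effects, numeric(3)))
      Dq <- genotypes$doses[, idx, drop = FALSE]
      Qc <- scale(Dq, center = TRUE, scale = FALSE) %*% B
      Cq <- crossprod(Qc) / (n - 1)
    } else {
      Qc <- matrix(0, n, q)
      Cq <- matrix(0, q, q)
    }
    G_target <- outer(sqrt(h2), sqrt(h2)) * config$genetic_correlations
    if (any(diag(Cq) >= h2))
      stop("invalid config: QTL variance meets or exceeds the target ",
           "genetic variance for at least one trait (heritability unreachable)")
    Sigma_u <- psd_clip(G_target - Cq, 1e-8)
    Sigma_e <- psd_clip(config$phenotypic_correlations - G_target, 1e-3)
    # drift can fix a few markers; monomorphics are silently skipped here
    K <- suppressWarnings(compute_kinship(genotypes))
    A <- K$values / mean(diag(K$values))
    L <- psd_factor(A, 1e-10)
    u <- L %*% matrix(stats::rnorm(n * q), n, q) %*% chol(Sigma_u)
    e <- matrix(stats::rnorm(n * q), n, q) %*% chol(Sigma_e)
    std <- Qc + u + e
    values <- sweep(sweep(std, 2, config$trait_sds, "*"),
                    2, config$trait_means, "+")
    colnames(values) <- config$trait_names
    out <- data.frame(id = genotypes$ids, values, stringsAsFactors = FALSE)
    attr(out, "components") <- list(qtl = Qc, polygenic = u, residual = e,
                                    Sigma_u = Sigma_u, Sigma_e = Sigma_e)
    out
  })
}
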