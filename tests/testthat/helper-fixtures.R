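# Shared fixtures: small genotype panels built in code, plus a reduced-size
# generator configuration for simulation-based checks.

tiny_genotypes <- function(n, m, seed = 1, chr = NULL, pos = NULL,
                           freq_range = c(0.2, 0.8)) {
  set.seed(seed)
  p <- runif(m, freq_range[1], freq_range[2])
  D <- sapply(p, function(pk) rbinom(n, 2, pk))
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(pos)) {
    pos <- numeric(m)
    for (cc in unique(chr)) pos[chr == cc] <- seq_len(sum(chr == cc))
  }
  map <- data.frame(snp = sprintf("s%03d", seq_len(m)), chr = chr, pos = pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  genotype_matrix(D, map, ids = sprintf("i%03d", seq_len(n)))
}

# Genotypes built from explicit dose columns (list of vectors).
geno_from_doses <- function(..., chr = NULL) {
  cols <- list(...)
  D <- do.call(cbind, cols)
  m <- ncol(D)
  if (is.null(chr)) chr <- rep(1L, m)
  map <- data.frame(snp = sprintf("s%03d", seq_len(m)), chr = chr,
                    pos = seq_len(m), a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  genotype_matrix(D, map, ids = sprintf("i%03d", seq_len(nrow(D))))
}

small_config <- function(seed, n = 300, snps = 120, founders = 40,
                         generations = 2, ...) {
  sim_config(n_individuals = n, snps_per_chromosome = snps,
             n_founder_haplotypes = founders, n_generations = generations,
             seed = seed, ...)
}

# All permutations of a vector, as a matrix with one permutation per row.
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    rest <- all_perms(v[-i])
    cbind(v[i], rest, deparse.level = 0)
  }))
}
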