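# Internal helpers: seeded evaluation, seed substreams, PSD repair, TSV output.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed derived from a master seed and a stream name,
# so independent stages (simulation, per-scan permutations, ...) can run in
# any order and still reproduce.  Result is a valid 32-bit integer seed.
substream_seed <- function(master, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((as.double(master) %% 65536 * 32003 + h) %% 2147483629L)
}

# Clip eigenvalues of a symmetric matrix from below; used both to repair a
# near-PSD kinship matrix before factorisation and to keep simulated
# covariance matrices valid.
psd_clip <- function(M, floor = 1e-8) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) >= floor) return(M)
  d <- pmax(ev$values, floor)
  out <- ev$vectors %*% (d * t(ev$vectors))
  (out + t(out)) / 2
}

# Symmetric matrix square root with eigenvalue floor (lower-triangular-like
# factor L with L %*% t(L) = clipped M).
psd_factor <- function(M, floor = 1e-10) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, floor)
  ev$vectors %*% diag(sqrt(d), length(d))
}

log_det_chol <- function(M) 2 * sum(log(diag(chol(M))))

# Headered TSV writer: comment lines record units and conventions so every
# emitted table is self-describing.
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
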