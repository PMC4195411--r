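# File formats.  Positions are carried in Mb internally; base pairs appear
# only at the PED/MAP boundary (MAP bp = Mb * 1e6).  All text outputs are
# plain headered TSV.

#' Write genotypes as PLINK PED + MAP
#'
#' The MAP file carries chromosome, SNP id, genetic distance (written as
#' 0), base-pair position (Mb x 1e6, rounded) and — as a documented
#' extension — two extra columns with the reference (counted) and
#' alternate allele, so the dose coding round-trips exactly.  The PED file
#' has the standard six leading columns (family and individual id set to
#' the individual id, unknown parents/sex, missing phenotype) followed by
#' two allele calls per SNP.
#'
#' @param genotypes A [genotype_matrix()] object.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotypes"))
  map <- genotypes$map
  map_out <- data.frame(chr = map$chr, snp = map$snp, cm = 0,
                        bp = as.integer(round(map$pos * 1e6)),
                        a1 = map$a1, a2 = map$a2)
  utils::write.table(map_out, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  D <- genotypes$doses
  n <- nrow(D); m <- ncol(D)
  a1 <- map$a1; a2 <- map$a2
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    first <- ifelse(is.na(d), "0", ifelse(d >= 1, a1, a2))
    second <- ifelse(is.na(d), "0", ifelse(d == 2, a1, a2))
    calls <- character(2 * m)
    calls[seq(1, 2 * m, 2)] <- first
    calls[seq(2, 2 * m, 2)] <- second
    lines[i] <- paste(c(genotypes$ids[i], genotypes$ids[i], "0", "0", "0",
                        "-9", calls), collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read genotypes from PLINK PED + MAP
#'
#' Accepts the standard 4-column MAP or the extended 6-column MAP written
#' by [write_ped_map()].  With 4 columns the reference allele of each SNP
#' is the lexicographically smaller allele observed there (documented
#' convention; the kinship and association statistics are invariant to the
#' choice).  Doses count the reference allele; `0` allele calls become
#' missing.  Base-pair positions are converted to Mb.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [genotype_matrix()] object.
#' @export
read_ped_map <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path))
    if (!file.exists(p)) stop("file not found: ", p)
  map_raw <- utils::read.table(map_path, stringsAsFactors = FALSE)
  if (!ncol(map_raw) %in% c(4, 6))
    stop("read_ped_map: MAP must have 4 or 6 columns, found ", ncol(map_raw))
  m <- nrow(map_raw)
  fields <- utils::count.fields(ped_path)
  expected <- 6 + 2 * m
  bad <- which(fields != expected)
  if (length(bad))
    stop(sprintf("read_ped_map: malformed PED row at line %d (%d fields, expected %d)",
                 bad[1], fields[bad[1]], expected))
  ped <- utils::read.table(ped_path, colClasses = "character",
                           stringsAsFactors = FALSE)
  ids <- ped[[2]]
  if (anyDuplicated(ids))
    stop("read_ped_map: duplicated individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- nrow(ped)
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a_first <- al[, seq(1, 2 * m, 2), drop = FALSE]
  a_second <- al[, seq(2, 2 * m, 2), drop = FALSE]
  have_alleles <- ncol(map_raw) == 6
  a1 <- character(m); a2 <- character(m)
  doses <- matrix(NA_real_, n, m)
  for (k in seq_len(m)) {
    obs <- c(a_first[, k], a_second[, k])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2)
      stop(sprintf("read_ped_map: SNP %s (column %d) has %d alleles",
                   map_raw[k, 2], k, length(alleles)))
    if (have_alleles) {
      a1[k] <- as.character(map_raw[k, 5]); a2[k] <- as.character(map_raw[k, 6])
      extra <- setdiff(alleles, c(a1[k], a2[k]))
      if (length(extra))
        stop(sprintf("read_ped_map: SNP %s carries allele(s) %s not in the MAP",
                     map_raw[k, 2], paste(extra, collapse = ",")))
    } else {
      a1[k] <- if (length(alleles) >= 1) alleles[1] else "A"
      a2[k] <- if (length(alleles) >= 2) alleles[2] else "B"
    }
    miss <- a_first[, k] == "0" | a_second[, k] == "0"
    doses[, k] <- (a_first[, k] == a1[k]) + (a_second[, k] == a1[k])
    doses[miss, k] <- NA_real_
  }
  map <- data.frame(snp = as.character(map_raw[[2]]),
                    chr = as.integer(map_raw[[1]]),
                    pos = as.numeric(map_raw[[4]]) / 1e6,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_matrix(doses, map, ids = ids)
}

#' Write genotypes as a dose TSV pair
#'
#' `<prefix>.dose.tsv` holds the allele-dose matrix (column `id` then one
#' column per SNP, entries 0/1/2 = copies of the reference allele);
#' `<prefix>.map.tsv` holds the SNP map (snp, chr, pos in Mb, a1, a2).
#'
#' @param genotypes A [genotype_matrix()] object.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_dose_tsv <- function(genotypes, prefix) {
  stopifnot(inherits(genotypes, "genotypes"))
  d <- data.frame(id = genotypes$ids, genotypes$doses,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, paste0(prefix, ".dose.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$map, paste0(prefix, ".map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read genotypes from a dose TSV pair
#'
#' @param prefix Path prefix of `<prefix>.dose.tsv` / `<prefix>.map.tsv`
#'   (see [write_dose_tsv()]).
#' @return A [genotype_matrix()] object.
#' @export
read_dose_tsv <- function(prefix) {
  dose_path <- paste0(prefix, ".dose.tsv")
  map_path <- paste0(prefix, ".map.tsv")
  for (p in c(dose_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  d <- read_tsv_plain(dose_path)
  map <- read_tsv_plain(map_path)
  D <- as.matrix(d[, -1, drop = FALSE])
  if (!identical(colnames(D), map$snp))
    stop("read_dose_tsv: dose columns do not match the map")
  genotype_matrix(D, map, ids = as.character(d$id))
}

#' Read genotypes (dispatch on format)
#'
#' @param prefix Path prefix.
#' @param format `"ped"` (PLINK PED/MAP) or `"dose"` (dose TSV pair).
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(prefix, format = c("ped", "dose")) {
  switch(match.arg(format), ped = read_ped_map(prefix),
         dose = read_dose_tsv(prefix))
}

#' Write genotypes (dispatch on format)
#'
#' @param genotypes A [genotype_matrix()] object.
#' @param prefix Output path prefix.
#' @param format `"ped"` or `"dose"`.
#' @return The prefix, invisibly.
#' @export
write_genotypes <- function(genotypes, prefix, format = c("ped", "dose")) {
  switch(match.arg(format), ped = write_ped_map(genotypes, prefix),
         dose = write_dose_tsv(genotypes, prefix))
}

#' Read a phenotype TSV (id column + one column per trait)
#'
#' @param path File path.
#' @return Data frame with character `id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv_plain(path)
  if (!"id" %in% names(df)) stop("read_phenotypes: no 'id' column in ", path)
  df$id <- as.character(df$id)
  for (nm in setdiff(names(df), "id")) {
    df[[nm]] <- as.numeric(df[[nm]])
    if (anyNA(df[[nm]]))
      stop("read_phenotypes: missing or non-numeric values in column ", nm)
  }
  df
}

#' Write a phenotype TSV
#'
#' @param phenotypes Data frame with an `id` column plus trait columns.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot("id" %in% names(phenotypes))
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
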