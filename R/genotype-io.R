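CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom == "23"] <- "X"
  chrom[chrom == "24"] <- "Y"
  if (!all(chrom %in% CHROM_LEVELS))
    stop_invalid("unknown chromosome label(s): %s",
                 paste(unique(setdiff(chrom, CHROM_LEVELS)), collapse = ", "))
  chrom
}

#' Pseudo-haploid genotype matrix
#'
#' The canonical in-memory representation of the pipeline: one pseudo-haploid
#' call per SNP per individual, `0` = reference allele, `1` = alternative
#' allele, `NA` = missing. SNPs are sorted by (chromosome, position) with
#' chromosomes ordered 1-22, X, Y.
#'
#' @param calls n_snps x n_individuals integer matrix with values in
#'   `{0, 1, NA}`.
#' @param snp data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param ind data frame with columns `label`, `sex` (M/F/U), `group`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp, ind) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L) | is.na(calls)))
    stop_invalid("calls must be 0, 1 or NA")
  if (nrow(calls) != nrow(snp))
    stop_invalid("calls has %d rows but snp table has %d", nrow(calls), nrow(snp))
  if (ncol(calls) != nrow(ind))
    stop_invalid("calls has %d columns but ind table has %d", ncol(calls), nrow(ind))
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(snp)),
            all(c("label", "sex", "group") %in% names(ind)))
  snp$chrom <- normalize_chrom(snp$chrom)
  if (any(snp$pos < 1)) stop_invalid("positions must be >= 1 (1-based)")
  ord <- order(match(snp$chrom, CHROM_LEVELS), snp$pos)
  snp <- snp[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  rownames(snp) <- NULL
  rownames(ind) <- NULL
  colnames(calls) <- ind$label
  structure(list(calls = calls, snp = snp, ind = ind),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read EIGENSTRAT geno/snp/ind files
#'
#' Expects the usual trio `<prefix>.geno` (one line of digits per SNP, one
#' digit per individual: alternative-allele count, 9 = missing),
#' `<prefix>.snp` (whitespace-delimited: id, chromosome, genetic position,
#' physical position, ref, alt) and `<prefix>.ind` (label, sex, group).
#' Pseudo-haploid data carry only the digits 0/2/9, normalized here to
#' 0/1/NA; a heterozygote digit 1 in a declared pseudo-haploid dataset is set
#' to missing with a warning (diploid reference merges do occur in practice).
#' Chromosome codes 23/24 are normalized to X/Y.
#'
#' @param prefix path prefix of the three files.
#' @return a [genotype_matrix()].
#' @export
read_eigenstrat <- function(prefix) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop_invalid("missing file: %s", p)
  ind <- read.table(paths[3L], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("label", "sex", "group"))
  empty_snp <- length(readLines(paths[2L], n = 1L)) == 0L
  if (empty_snp) {
    snp <- data.frame(id = character(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  } else {
    snp_raw <- read.table(paths[2L], header = FALSE, stringsAsFactors = FALSE)
    if (ncol(snp_raw) != 6L)
      stop_invalid("%s: expected 6 columns, found %d", paths[2L], ncol(snp_raw))
    snp <- data.frame(id = as.character(snp_raw[[1L]]),
                      chrom = as.character(snp_raw[[2L]]),
                      pos = as.integer(snp_raw[[4L]]),
                      ref = as.character(snp_raw[[5L]]),
                      alt = as.character(snp_raw[[6L]]),
                      stringsAsFactors = FALSE)
  }
  lines <- readLines(paths[1L])
  if (length(lines) != nrow(snp))
    stop_invalid("%s: %d genotype lines but %d SNP records",
                 paths[1L], length(lines), nrow(snp))
  n <- nrow(ind)
  bad <- which(nchar(lines) != n)
  if (length(bad))
    stop_invalid("%s: line %d has %d digits but there are %d individuals",
                 paths[1L], bad[1L], nchar(lines[bad[1L]]), n)
  digits <- matrix(as.integer(unlist(strsplit(lines, "", fixed = TRUE),
                                     use.names = FALSE)),
                   nrow = length(lines), ncol = n, byrow = TRUE)
  if (!all(digits %in% c(0L, 1L, 2L, 9L)))
    stop_invalid("%s: genotype digits must be 0/1/2/9", paths[1L])
  n_het <- sum(digits == 1L)
  if (n_het > 0L)
    warning(sprintf(
      "%d heterozygote call(s) in pseudo-haploid dataset set to missing",
      n_het), call. = FALSE)
  calls <- matrix(NA_integer_, nrow(digits), ncol(digits))
  calls[digits == 0L] <- 0L
  calls[digits == 2L] <- 1L
  genotype_matrix(calls, snp, ind)
}

#' Write EIGENSTRAT geno/snp/ind files
#'
#' Inverse of [read_eigenstrat()]: calls 0/1/NA serialize to digits 0/2/9.
#' `read_eigenstrat(write_eigenstrat(m))` reproduces `m`.
#'
#' @param matrix a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  digits <- matrix$calls
  out <- base::matrix("9", nrow(digits), ncol(digits))
  out[!is.na(digits) & digits == 0L] <- "0"
  out[!is.na(digits) & digits == 1L] <- "2"
  lines <- if (nrow(out) == 0L) character() else
    apply(out, 1L, paste, collapse = "")
  writeLines(lines, paste0(prefix, ".geno"))
  snp_out <- data.frame(matrix$snp$id, matrix$snp$chrom,
                        rep(0, nrow(matrix$snp)),
                        matrix$snp$pos, matrix$snp$ref, matrix$snp$alt)
  write.table(snp_out, paste0(prefix, ".snp"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  write.table(matrix$ind, paste0(prefix, ".ind"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Apply the individual-retention filter
#'
#' Keeps individuals with strictly more than `min_snps` non-missing calls
#' (the capture-panel retention rule for low-coverage individuals).
#'
#' @param matrix a [genotype_matrix()].
#' @param min_snps retention threshold (default 20000; strict inequality).
#' @return list with `matrix` (filtered) and `report` (per-individual label,
#'   non-missing call count, kept flag).
#' @export
filter_individuals <- function(matrix, min_snps = 20000L) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  covered <- colSums(!is.na(matrix$calls))
  keep <- covered > min_snps
  report <- data.frame(label = matrix$ind$label,
                       n_snps_covered = as.integer(covered),
                       kept = keep, stringsAsFactors = FALSE)
  out <- genotype_matrix(matrix$calls[, keep, drop = FALSE],
                         matrix$snp, matrix$ind[keep, , drop = FALSE])
  list(matrix = out, report = report)
}
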