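#' Apply selection-scan site and individual filters
#'
#' Sex chromosomes are dropped, individuals with more than
#' `max_ind_missing` missingness are removed, and SNPs with pooled minor
#' allele frequency below `maf_min` (computed over non-missing calls of the
#' retained individuals; monomorphic sites have MAF 0) are excluded.
#'
#' @param matrix a [genotype_matrix()].
#' @param maf_min minimum pooled minor allele frequency (default 0.01).
#' @param max_ind_missing maximum per-individual missingness fraction
#'   (default 0.97; strictly greater is removed).
#' @return a filtered [genotype_matrix()] (possibly empty, with a warning).
#' @export
site_filters <- function(matrix, maf_min = 0.01, max_ind_missing = 0.97) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  auto <- !(matrix$snp$chrom %in% c("X", "Y"))
  calls <- matrix$calls[auto, , drop = FALSE]
  snp <- matrix$snp[auto, , drop = FALSE]
  miss <- colMeans(is.na(calls))
  keep_ind <- miss <= max_ind_missing
  calls <- calls[, keep_ind, drop = FALSE]
  ind <- matrix$ind[keep_ind, , drop = FALSE]
  f <- rowMeans(calls, na.rm = TRUE)
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep_snp <- maf >= maf_min
  if (!any(keep_snp) || !any(keep_ind))
    warning("site_filters produced an empty matrix", call. = FALSE)
  genotype_matrix(calls[keep_snp, , drop = FALSE],
                  snp[keep_snp, , drop = FALSE], ind)
}

# r^2 between two 0/1 call vectors over jointly non-missing individuals;
# undefined (constant) vectors give 0 so the pair is never pruned on them.
call_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(0)
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

#' LD pruning with a sliding SNP window
#'
#' plink-style `--indep-pairwise` pruning on pseudo-haploid calls: within a
#' sliding window of `window_snps` SNPs advanced by `step_snps`, while any
#' retained pair has r-squared above `r2_max`, the member with the lower
#' pooled MAF is dropped (ties drop the later position). r-squared is the
#' squared correlation of the 0/1 call vectors over jointly non-missing
#' individuals (calls are haploid draws; no diploid dosage exists). The
#' result is stable: re-pruning the retained set changes nothing.
#'
#' @param matrix a [genotype_matrix()], SNPs position-sorted (guaranteed by
#'   construction).
#' @param window_snps,step_snps window size and step in SNPs (defaults
#'   200 / 25).
#' @param r2_max r-squared threshold (default 0.4).
#' @return integer vector of retained SNP row indices into `matrix$snp`.
#' @export
ld_prune <- function(matrix, window_snps = 200L, step_snps = 25L,
                     r2_max = 0.4) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  f <- rowMeans(calls, na.rm = TRUE)
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  keep <- rep(TRUE, nrow(calls))
  for (chr in unique(matrix$snp$chrom)) {
    snps <- which(matrix$snp$chrom == chr)
    starts <- seq(1L, length(snps), by = step_snps)
    for (s in starts) {
      win <- snps[s:min(s + window_snps - 1L, length(snps))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        dropped <- FALSE
        for (a in seq_len(length(act) - 1L)) {
          for (b in seq((a + 1L), length(act))) {
            i <- act[a]; j <- act[b]
            if (!keep[i] || !keep[j]) next
            if (call_r2(calls[i, ], calls[j, ]) > r2_max) {
              # drop the lower-MAF member; ties drop the later position
              drop <- if (maf[i] < maf[j]) i
                      else if (maf[j] < maf[i]) j
                      else j
              keep[drop] <- FALSE
              dropped <- TRUE
            }
          }
        }
        if (!dropped) break
      }
    }
  }
  which(keep)
}

#' Hudson's pairwise FST estimator
#'
#' Per-SNP FST distance with sample-size correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. The raw (possibly negative) value is returned;
#' clip at 0 before branch-length decomposition. Sites with fewer than 2
#' called alleles in either population give `NA`.
#'
#' @param p1,p2 allele frequency estimates (vectors).
#' @param n1,n2 called-allele totals (vectors or scalars).
#' @return numeric vector of raw distances.
#' @export
pairwise_fst <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  d <- ifelse(den > 0, num / den, NA_real_)
  d[n1 <= 1 | n2 <= 1] <- NA_real_
  d
}

#' Locus-specific branch length decomposition
#'
#' Decomposes the three pairwise distances among populations A, B, C into
#' branch lengths: `x = (d_AB + d_AC - d_BC)/2` (A's branch),
#' `y = (d_AB + d_BC - d_AC)/2` (B's), `z = (d_AC + d_BC - d_AB)/2` (C's).
#' Negative branches are permitted and reported raw;
#' `x + y + z = (d_AB + d_BC + d_AC)/2` exactly.
#'
#' @param d_ab,d_bc,d_ac pairwise distances (vectors).
#' @return data frame with columns `x`, `y`, `z`.
#' @export
lsbl_decompose <- function(d_ab, d_bc, d_ac) {
  data.frame(x = (d_ab + d_ac - d_bc) / 2,
             y = (d_ab + d_bc - d_ac) / 2,
             z = (d_ac + d_bc - d_ab) / 2)
}

#' Flag empirical outlier tails
#'
#' Thresholds are the k-th largest values with `k = max(1, floor(n * tail))`;
#' every value greater than or equal to the threshold is flagged, so ties at
#' the threshold are all included and the tails are nested.
#'
#' @param values numeric vector of branch lengths.
#' @param tails tail fractions, largest-to-smallest nesting implied
#'   (default top 0.5% and top 0.1%).
#' @return character vector: `"none"`, `"top0.5"` or `"top0.1"` (the tightest
#'   tail each value reaches) for the default tails; generally
#'   `"top<100*tail>"`.
#' @export
empirical_outliers <- function(values, tails = c(0.005, 0.001)) {
  n <- length(values)
  if (n < 1L) stop_invalid("no values to flag")
  tails <- sort(tails, decreasing = TRUE)
  flags <- rep("none", n)
  srt <- sort(values, decreasing = TRUE)
  warned <- FALSE
  for (tail in tails) {
    k <- max(1L, floor(n * tail))
    thr <- srt[k]
    hit <- values >= thr
    if (all(hit) && !warned) {
      warning("degenerate branch distribution: all values tie at the threshold",
              call. = FALSE)
      warned <- TRUE
    }
    flags[hit] <- sprintf("top%g", 100 * tail)
  }
  flags
}

#' Run the three-population LSBL scan on frequency tables
#'
#' Computes Hudson FST distances for the three population pairs, clips
#' negative distances at 0 (raw values retained in the output), decomposes
#' into branch lengths and flags empirical tails per branch.
#'
#' @param A,B,C data frames with columns `count`, `total`, `freq` (one row
#'   per SNP, same order), e.g. from [simulate_selection_shift()] or
#'   [pop_frequencies()].
#' @param tails tail fractions for [empirical_outliers()].
#' @return data frame: raw `d_AB`, `d_BC`, `d_AC`, branch lengths `x`, `y`,
#'   `z`, and per-branch tail flags `tail_A`, `tail_B`, `tail_C`.
#' @export
lsbl_scan <- function(A, B, C, tails = c(0.005, 0.001)) {
  d_ab <- pairwise_fst(A$freq, A$total, B$freq, B$total)
  d_bc <- pairwise_fst(B$freq, B$total, C$freq, C$total)
  d_ac <- pairwise_fst(A$freq, A$total, C$freq, C$total)
  br <- lsbl_decompose(pmax(d_ab, 0), pmax(d_bc, 0), pmax(d_ac, 0))
  ok <- !is.na(br$x)
  flag <- function(v) {
    out <- rep(NA_character_, length(v))
    out[ok] <- empirical_outliers(v[ok], tails)
    out
  }
  data.frame(d_AB = d_ab, d_BC = d_bc, d_AC = d_ac,
             x = br$x, y = br$y, z = br$z,
             tail_A = flag(br$x), tail_B = flag(br$y), tail_C = flag(br$z),
             stringsAsFactors = FALSE)
}

#' Per-population allele frequencies from a genotype matrix
#'
#' Pseudo-haploid calls are counted as single alleles: per SNP and
#' population, `count` alternative alleles out of `total` non-missing calls.
#'
#' @param matrix a [genotype_matrix()].
#' @param groups optional grouping vector (defaults to the ind-table `group`
#'   column).
#' @return named list of data frames (`count`, `total`, `freq`), one per
#'   group, rows in SNP order.
#' @export
pop_frequencies <- function(matrix, groups = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  groups <- groups %||% matrix$ind$group
  out <- lapply(unique(groups), function(g) {
    calls <- matrix$calls[, groups == g, drop = FALSE]
    total <- rowSums(!is.na(calls))
    count <- rowSums(calls == 1L, na.rm = TRUE)
    data.frame(count = count, total = total,
               freq = ifelse(total > 0, count / total, NA_real_))
  })
  setNames(out, unique(groups))
}
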