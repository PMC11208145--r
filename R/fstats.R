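# Delete-one block jackknife over contiguous SNP blocks. The estimate is the
# plain mean of per-SNP terms (invariant to the block partition); the SE
# comes from leave-one-block-out recomputation.
block_jackknife <- function(terms, block_size) {
  n <- length(terms)
  blocks <- ((seq_len(n) - 1L) %/% block_size) + 1L
  g <- max(blocks)
  est <- mean(terms)
  if (g < 2L)
    return(list(estimate = est, se = NA_real_, n_blocks = g))
  total <- sum(terms)
  loo <- vapply(seq_len(g), function(j) {
    sel <- blocks == j
    (total - sum(terms[sel])) / (n - sum(sel))
  }, 0)
  se <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, n_blocks = g)
}

fstat_result <- function(statistic, populations, terms, block_size) {
  jk <- block_jackknife(terms, block_size)
  structure(list(statistic = statistic, populations = populations,
                 estimate = jk$estimate, jackknife_se = jk$se,
                 z = if (!is.na(jk$se) && jk$se > 0) jk$estimate / jk$se
                     else NA_real_,
                 n_snps_used = length(terms), n_blocks = jk$n_blocks),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.3g  (%d SNPs, %d blocks)\n",
              x$statistic, paste(x$populations, collapse = ", "),
              x$estimate, x$jackknife_se, x$z, x$n_snps_used, x$n_blocks))
  invisible(x)
}

#' Outgroup f3 statistic with block-jackknife error
#'
#' `f3(O; A, B)` measures shared drift of A and B after divergence from the
#' outgroup O: the mean over SNPs of `(p_O - p_A)(p_O - p_B)`. SNPs with any
#' of the three frequencies missing are dropped (complete case). The standard
#' error is a delete-one block jackknife over contiguous SNP blocks. No
#' within-population heterozygosity correction is applied by default:
#' outgroup-f3 affinity rankings against a fixed (O, A) are unaffected by the
#' shared offset.
#'
#' @param p_o,p_a,p_b per-SNP allele frequencies.
#' @param block_size_snps jackknife block size in SNPs (default 500).
#' @param populations labels for reporting.
#' @return an `fstat_result` (estimate, jackknife SE, Z, SNP/block counts).
#' @export
outgroup_f3 <- function(p_o, p_a, p_b, block_size_snps = 500L,
                        populations = c("O", "A", "B")) {
  ok <- !is.na(p_o) & !is.na(p_a) & !is.na(p_b)
  if (!any(ok)) stop_invalid("no SNPs with all three populations called")
  terms <- (p_o[ok] - p_a[ok]) * (p_o[ok] - p_b[ok])
  fstat_result("f3", populations, terms, block_size_snps)
}

#' f4 statistic with block-jackknife error
#'
#' `f4(A, B; C, D)` is the mean over SNPs of `(p_A - p_B)(p_C - p_D)`; zero
#' under treeness of ((A,B),(C,D)), antisymmetric under swapping within
#' either pair. Complete-case over the four populations; SE by delete-one
#' block jackknife.
#'
#' @param p_a,p_b,p_c,p_d per-SNP allele frequencies.
#' @param block_size_snps jackknife block size in SNPs (default 500).
#' @param populations labels for reporting.
#' @return an `fstat_result`.
#' @export
f4 <- function(p_a, p_b, p_c, p_d, block_size_snps = 500L,
               populations = c("A", "B", "C", "D")) {
  ok <- !is.na(p_a) & !is.na(p_b) & !is.na(p_c) & !is.na(p_d)
  if (!any(ok)) stop_invalid("no SNPs with all four populations called")
  terms <- (p_a[ok] - p_b[ok]) * (p_c[ok] - p_d[ok])
  fstat_result("f4", populations, terms, block_size_snps)
}
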