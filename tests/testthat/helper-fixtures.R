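# Small programmatic fixtures shared across test files.

# genotype matrix from a plain call matrix (rows = SNPs, cols = individuals)
gm_from_calls <- function(calls, chrom = NULL, group = "cohort") {
  n_snp <- nrow(calls)
  snp <- data.frame(id = sprintf("rs%d", seq_len(n_snp)),
                    chrom = chrom %||% rep("1", n_snp),
                    pos = seq_len(n_snp) * 100L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  labels <- colnames(calls) %||% sprintf("ind%d", seq_len(ncol(calls)))
  ind <- data.frame(label = labels, sex = "U",
                    group = rep_len(group, ncol(calls)),
                    stringsAsFactors = FALSE)
  genotype_matrix(calls, snp, ind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-haplotype HLA pool over two loci used by the shift simulations
hla_test_pool <- function() {
  data.frame(
    DRB1 = c("DRB1*04:07", "DRB1*14:02", "DRB1*08:02", "DRB1*16:02"),
    DQB1 = c("DQB1*03:02", "DQB1*03:01", "DQB1*04:02", "DQB1*03:01"),
    freq = c(0.234, 0.3, 0.3, 0.166),
    stringsAsFactors = FALSE)
}

# independent two-sided Fisher p by hypergeometric enumeration: sum the
# probabilities of all tables with the same margins whose probability does
# not exceed the observed table's
fisher_p_enum <- function(c1, t1, c2, t2) {
  k <- c1 + c2
  lo <- max(0L, k - t2)
  hi <- min(k, t1)
  probs <- dhyper(lo:hi, t1, t2, k)
  obs <- dhyper(c1, t1, t2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# literal BH step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
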