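HLA_LOCI <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

valid_allele_name <- function(allele) {
  grepl("^[A-Z0-9]+\\*[0-9]+(:[0-9]+)+[A-Z]?$", allele)
}

#' Per-locus allele counts and frequencies for a cohort
#'
#' Each individual typed at a locus contributes exactly two alleles; untyped
#' individuals (absent rows or NA alleles) are excluded from that locus's
#' total. Allele names must follow field nomenclature (e.g. `DRB1*04:07`).
#'
#' @param genotypes data frame with columns `sample`, `locus`, `allele1`,
#'   `allele2`.
#' @param cohort cohort label recorded in the output.
#' @param loci loci to tabulate (default: all present).
#' @return data frame: `cohort`, `locus`, `allele`, `count`,
#'   `total_alleles`, `freq`.
#' @export
allele_frequencies <- function(genotypes, cohort = "cohort", loci = NULL) {
  stopifnot(all(c("sample", "locus", "allele1", "allele2") %in%
                  names(genotypes)))
  loci <- loci %||% unique(genotypes$locus)
  out <- list()
  for (L in loci) {
    rows <- genotypes[genotypes$locus == L, , drop = FALSE]
    alleles <- c(rows$allele1, rows$allele2)
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L) next
    if (!all(valid_allele_name(alleles)))
      stop_invalid("malformed allele name(s) at locus %s: %s", L,
                   paste(unique(alleles[!valid_allele_name(alleles)]),
                         collapse = ", "))
    if (length(alleles) %% 2L != 0L)
      stop_invalid("locus %s: odd number of alleles", L)
    tab <- table(alleles)
    out[[L]] <- data.frame(cohort = cohort, locus = L,
                           allele = names(tab), count = as.integer(tab),
                           total_alleles = length(alleles),
                           freq = as.integer(tab) / length(alleles),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(cohort = character(), locus = character(),
                      allele = character(), count = integer(),
                      total_alleles = integer(), freq = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher exact test for a 2x2 allele-count table
#'
#' Exact two-sided p by the minimum-likelihood method (sum of hypergeometric
#' probabilities no larger than the observed table's). The reported odds
#' ratio is the conditional maximum-likelihood estimate.
#'
#' @param count_1,total_1 allele count and total in cohort 1.
#' @param count_2,total_2 same for cohort 2.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(count_1, total_1, count_2, total_2) {
  if (total_1 <= 0 || total_2 <= 0) stop_invalid("zero totals")
  if (count_1 > total_1 || count_2 > total_2 || count_1 < 0 || count_2 < 0)
    stop_invalid("counts must satisfy 0 <= count <= total")
  tab <- matrix(c(count_1, total_1 - count_1, count_2, total_2 - count_2),
                nrow = 2L, byrow = TRUE)
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min over j >= i of (m * p_(j) / j)`, mapped
#' back to the input order.
#'
#' @param p vector of raw p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Test allele-frequency shifts between two cohorts
#'
#' One Fisher exact test per allele observed in either cohort, with the BH
#' family pooled across all loci (per-locus families available via
#' `family_per_locus`). Direction is the sign of the cohort-2 minus cohort-1
#' frequency difference.
#'
#' @param table_1,table_2 allele count tables from [allele_frequencies()].
#' @param alpha FDR significance level (default 0.05).
#' @param family_per_locus if `TRUE`, apply BH within each locus separately.
#' @return data frame: `locus`, `allele`, `freq_1`, `freq_2`, `odds_ratio`,
#'   `p_raw`, `q`, `direction`, `significant`.
#' @export
compare_cohorts <- function(table_1, table_2, alpha = 0.05,
                            family_per_locus = FALSE) {
  loci <- union(table_1$locus, table_2$locus)
  rows <- list()
  for (L in loci) {
    t1 <- table_1[table_1$locus == L, , drop = FALSE]
    t2 <- table_2[table_2$locus == L, , drop = FALSE]
    if (nrow(t1) == 0L || nrow(t2) == 0L) next
    n1 <- t1$total_alleles[1L]; n2 <- t2$total_alleles[1L]
    for (a in union(t1$allele, t2$allele)) {
      c1 <- if (a %in% t1$allele) t1$count[t1$allele == a] else 0L
      c2 <- if (a %in% t2$allele) t2$count[t2$allele == a] else 0L
      ft <- fisher_exact_2x2(c1, n1, c2, n2)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = L, allele = a, freq_1 = c1 / n1, freq_2 = c2 / n2,
        odds_ratio = ft$odds_ratio, p_raw = ft$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  if (family_per_locus) {
    res$q <- NA_real_
    for (L in unique(res$locus)) {
      sel <- res$locus == L
      res$q[sel] <- bh_adjust(res$p_raw[sel])
    }
  } else {
    res$q <- bh_adjust(res$p_raw)
  }
  res$direction <- ifelse(res$freq_2 > res$freq_1, "increase",
                          ifelse(res$freq_2 < res$freq_1, "decrease", "none"))
  res$significant <- res$q < alpha
  rownames(res) <- NULL
  res
}

#' Build a two-locus haplotype count table from phased haplotypes
#'
#' @param haplotypes long-format phased table: `sample`, `haplotype_index`
#'   (1/2), `locus`, `allele`.
#' @param locus1,locus2 the locus pair.
#' @return integer matrix of haplotype counts, rows = alleles at `locus1`,
#'   columns = alleles at `locus2`. Only haplotypes typed at both loci are
#'   counted.
#' @export
haplotype_pair_table <- function(haplotypes, locus1, locus2) {
  h1 <- haplotypes[haplotypes$locus == locus1, ]
  h2 <- haplotypes[haplotypes$locus == locus2, ]
  key <- function(h) paste(h$sample, h$haplotype_index, sep = "\r")
  m <- merge(data.frame(k = key(h1), a1 = h1$allele, stringsAsFactors = FALSE),
             data.frame(k = key(h2), a2 = h2$allele, stringsAsFactors = FALSE),
             by = "k")
  m <- m[!is.na(m$a1) & !is.na(m$a2), ]
  as.matrix(table(factor(m$a1), factor(m$a2)))
}

#' Non-overlap association score for a two-locus haplotype table
#'
#' Operationalization of the non-overlapping-association metric used to rank
#' HLA locus pairs (the published formula lives in external work; any
#' monotone non-overlap statistic plugs into the permutation wrapper, which
#' is the calibrated quantity). For each allele at one locus, its
#' association profile is the conditional allele distribution at the other
#' locus; the score is 1 minus the margin-frequency-weighted mean pairwise
#' overlap (sum of elementwise minima) of those profiles, averaged over both
#' locus orientations. Perfectly non-overlapping associations score 1
#' (maximal for the margins); under exact independence all profiles coincide
#' and the score is 0 in the large-sample limit, so it is 0-centred there.
#'
#' @param table haplotype count matrix (alleles at L1 x alleles at L2) with
#'   at least 2 alleles at each locus and total count >= 1.
#' @return single numeric score; `NA` with a `reason` attribute when the
#'   table is degenerate (a locus with a single observed allele).
#' @export
f_adj_star <- function(table) {
  table <- as.matrix(table)
  if (sum(table) < 1) stop_invalid("empty haplotype table")
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L)
    return(structure(NA_real_,
                     reason = "degenerate table: fewer than 2 alleles at a locus"))
  directional <- function(tab) {
    w <- rowSums(tab) / sum(tab)
    q <- tab / rowSums(tab)            # conditional profiles, rows
    k <- nrow(tab)
    num <- 0; den <- 0
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
      ov <- sum(pmin(q[a, ], q[b, ]))
      num <- num + w[a] * w[b] * ov
      den <- den + w[a] * w[b]
    }
    1 - num / den
  }
  unname((directional(table) + directional(t(table))) / 2)
}

#' Permutation null for the non-overlap score
#'
#' The haplotype table is expanded to its haplotype list, the allele labels
#' at the second locus are permuted across haplotypes (both allele margins
#' preserved exactly), and the score is recomputed per permutation. The
#' calibrated result is the observed score minus the null mean, in units of
#' the null standard deviation.
#'
#' @param table haplotype count matrix as for [f_adj_star()].
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list of class `non_overlap_score`: `f_adj_star`, `perm_mean`,
#'   `perm_sd`, `sd_units` (`NA` with a diagnostic when the null SD is 0),
#'   `n_permutations`, `seed`.
#' @export
permutation_null <- function(table, n_perm = 5000L, seed = 1L) {
  table <- as.matrix(table)
  observed <- f_adj_star(table)
  if (is.na(observed))
    stop_invalid("table is degenerate for the non-overlap score")
  idx <- which(table > 0, arr.ind = TRUE)
  a1 <- factor(rep(rownames(table)[idx[, 1L]], table[idx]),
               levels = rownames(table))
  a2 <- factor(rep(colnames(table)[idx[, 2L]], table[idx]),
               levels = colnames(table))
  set.seed(seed)
  null_scores <- vapply(seq_len(n_perm), function(i) {
    perm <- a2[sample.int(length(a2))]
    f_adj_star(as.matrix(table(a1, perm)))
  }, 0)
  pm <- mean(null_scores); ps <- sd(null_scores)
  structure(list(f_adj_star = observed, perm_mean = pm, perm_sd = ps,
                 sd_units = if (ps > 0) (observed - pm) / ps else NA_real_,
                 degenerate_null = ps <= 0,
                 n_permutations = n_perm, seed = seed),
            class = "non_overlap_score")
}

#' @export
print.non_overlap_score <- function(x, ...) {
  cat(sprintf("non-overlap score %.4f; null %.4f +/- %.4f; %.2f SD units (%d perms)\n",
              x$f_adj_star, x$perm_mean, x$perm_sd,
              if (is.na(x$sd_units)) NA else x$sd_units, x$n_permutations))
  invisible(x)
}
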