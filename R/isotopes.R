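#' Collagen quality control
#'
#' A record passes when collagen yield is strictly above 1% by weight and
#' the atomic C:N ratio lies in the inclusive range 2.9-3.6. Records with
#' missing yield or C:N are flagged unevaluable (`qc_pass = NA`).
#'
#' @param records data frame with columns `sample`, `d13C`, `d15N`,
#'   `collagen_yield`, `cn_ratio`.
#' @return the input with `qc_pass` (logical) and `qc_reason` columns added.
#' @export
collagen_qc <- function(records) {
  need <- c("sample", "d13C", "d15N", "collagen_yield", "cn_ratio")
  stopifnot(all(need %in% names(records)))
  yield_ok <- records$collagen_yield > 1
  cn_ok <- records$cn_ratio >= 2.9 & records$cn_ratio <= 3.6
  pass <- yield_ok & cn_ok
  fail_y <- yield_ok %in% FALSE
  fail_c <- cn_ok %in% FALSE
  reason <- rep("", nrow(records))
  reason[fail_y & !fail_c] <- "yield"
  reason[!fail_y & fail_c] <- "cn_ratio"
  reason[fail_y & fail_c] <- "yield;cn_ratio"
  unevaluable <- is.na(records$collagen_yield) | is.na(records$cn_ratio)
  pass[unevaluable] <- NA
  reason[unevaluable] <- "unevaluable"
  records$qc_pass <- pass
  records$qc_reason <- reason
  records
}

#' Cohort summary of an isotope field
#'
#' Summarizes QC-passing records only; `sd` is the sample standard deviation
#' (n - 1 denominator).
#'
#' @param records output of [collagen_qc()].
#' @param field column to summarize (e.g. `"d13C"`).
#' @return list: `n`, `min`, `max`, `mean`, `sd`; all `NA` (n = 0) when no
#'   record passes QC.
#' @export
cohort_summary <- function(records, field) {
  if (is.null(records$qc_pass))
    stop_invalid("run collagen_qc() first")
  x <- records[[field]][records$qc_pass %in% TRUE]
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(list(n = 0L, min = NA_real_, max = NA_real_, mean = NA_real_,
                sd = NA_real_))
  list(n = length(x), min = min(x), max = max(x), mean = mean(x),
       sd = if (length(x) > 1L) sd(x) else 0)
}

#' Dietary similarity of related pairs
#'
#' Observed statistic: mean pairwise Euclidean distance in the
#' (delta13C, delta15N) plane over close relative pairs (degree <= second)
#' with isotope data. The null permutes sample labels on the isotope records
#' (relationships fixed, diets shuffled); the one-sided p-value is the
#' add-one-corrected proportion of permutations with mean distance less than
#' or equal to the observed (small distances = dietary similarity).
#'
#' @param records output of [collagen_qc()]; only QC-passing records are
#'   used.
#' @param calls relatedness calls from [classify_pairs()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param weights length-2 weights for the (d13C, d15N) axes (default equal).
#' @return list: `n_pairs_used`, `observed_mean_distance`, `p`, or an
#'   `applicable = FALSE` result when no close pair has isotope data.
#' @export
related_pair_similarity <- function(records, calls, n_perm = 10000L,
                                    seed = 1L, weights = c(1, 1)) {
  if (is.null(records$qc_pass)) records <- collagen_qc(records)
  recs <- records[records$qc_pass %in% TRUE, , drop = FALSE]
  close <- calls[!is.na(calls$degree) &
                   calls$degree %in% c("identical", "first", "second"), ,
                 drop = FALSE]
  usable <- close$sample_i %in% recs$sample & close$sample_j %in% recs$sample
  close <- close[usable, , drop = FALSE]
  if (nrow(close) == 0L)
    return(list(applicable = FALSE, n_pairs_used = 0L,
                observed_mean_distance = NA_real_, p = NA_real_))
  xy <- cbind(recs$d13C * weights[1L], recs$d15N * weights[2L])
  rownames(xy) <- recs$sample
  i <- match(close$sample_i, recs$sample)
  j <- match(close$sample_j, recs$sample)
  mean_dist <- function(mat) {
    mean(sqrt(rowSums((mat[i, , drop = FALSE] - mat[j, , drop = FALSE])^2)))
  }
  obs <- mean_dist(xy)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(k) {
    mean_dist(xy[sample.int(nrow(xy)), , drop = FALSE])
  }, 0)
  p <- (1 + sum(perm_stats <= obs)) / (n_perm + 1)
  list(applicable = TRUE, n_pairs_used = nrow(close),
       observed_mean_distance = obs, p = p, seed = seed)
}
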