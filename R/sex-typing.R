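#' Compute X/Y coverage rates relative to autosomes
#'
#' For each sample, per-site depth on X (and Y) is divided by per-site
#' autosomal depth, normalizing each chromosome class by its targeted-site
#' count: `x_rate = (X reads / X sites) / (autosomal reads / autosomal
#' sites)`, analogously for Y. Males are expected near (0.5, 0.5), females
#' near (1, 0).
#'
#' @param coverage long-format coverage table with columns `sample`,
#'   `chromosome_class` (autosome/X/Y), `sites_covered`, `total_reads`
#'   (as produced by [simulate_sex_coverage()] or read from TSV).
#' @return data frame: `sample`, `x_rate`, `y_rate`, `sex_call` (all `NA`,
#'   set by [assign_sex()]).
#' @export
compute_rates <- function(coverage) {
  stopifnot(all(c("sample", "chromosome_class", "sites_covered",
                  "total_reads") %in% names(coverage)))
  samples <- unique(coverage$sample)
  per_site <- function(rows, class) {
    r <- rows[rows$chromosome_class == class, , drop = FALSE]
    if (nrow(r) == 0L) stop_invalid("no %s coverage rows", class)
    sum(r$total_reads) / sum(r$sites_covered)
  }
  out <- lapply(samples, function(s) {
    rows <- coverage[coverage$sample == s, , drop = FALSE]
    auto <- per_site(rows, "autosome")
    if (auto <= 0)
      stop_invalid("sample %s has zero autosomal coverage; rates undefined", s)
    data.frame(sample = s, x_rate = per_site(rows, "X") / auto,
               y_rate = per_site(rows, "Y") / auto,
               sex_call = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign genetic sex from coverage rates
#'
#' A sample is called male when both rates fall inside the male confirmation
#' windows (X rate in `[0.35, 0.55]`, Y rate in `[0.4, 0.7]`; bounds
#' inclusive), female when `x_rate >= 0.8` and `y_rate <= 0.1`, and
#' indeterminate otherwise. The female window follows standard practice for
#' capture data and is configurable.
#'
#' @param rates data frame from [compute_rates()].
#' @param male_x,male_y inclusive (low, high) windows for the male call.
#' @param female_x_min,female_y_max female thresholds.
#' @return `rates` with `sex_call` filled in
#'   (male/female/indeterminate).
#' @export
assign_sex <- function(rates, male_x = c(0.35, 0.55), male_y = c(0.4, 0.7),
                       female_x_min = 0.8, female_y_max = 0.1) {
  male <- rates$x_rate >= male_x[1L] & rates$x_rate <= male_x[2L] &
    rates$y_rate >= male_y[1L] & rates$y_rate <= male_y[2L]
  female <- rates$x_rate >= female_x_min & rates$y_rate <= female_y_max
  rates$sex_call <- ifelse(male, "male",
                           ifelse(female, "female", "indeterminate"))
  rates
}
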