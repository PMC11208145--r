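#!/usr/bin/env Rscript
# Step 2 — genetic sexing and PMR kinship on the simulated cohort.
#
# Reads the EIGENSTRAT cohort and coverage table from step 1, applies the
# >20,000-SNP retention filter, calls genetic sex from X/Y coverage rates,
# computes pairwise mismatch rates, normalizes against the cohort median and
# classifies relationship degrees. Writes per-sample sex calls, the
# pair-level kinship table and a summary JSON under results/.

library(chultun)

dir.create("results", showWarnings = FALSE)
gm <- read_eigenstrat("results/cohort/chultun_like")
flt <- filter_individuals(gm, min_snps = 20000L)
cat(sprintf("retention filter: %d of %d individuals kept (>20000 SNPs)\n",
            sum(flt$report$kept), nrow(flt$report)))
gm <- flt$matrix

cov <- read.table("results/cohort/coverage.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
sex_calls <- assign_sex(compute_rates(cov))
write.table(sex_calls, "results/sex_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("sexing: %d male, %d female, %d indeterminate\n",
            sum(sex_calls$sex_call == "male"),
            sum(sex_calls$sex_call == "female"),
            sum(sex_calls$sex_call == "indeterminate")))

pm <- normalize_background(pairwise_mismatch_rate(gm, min_overlap = 5000L))
calls <- classify_pairs(pm)
write.table(calls, "results/kinship_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- summarize_relatedness(calls)
jsonlite::write_json(s, "results/kinship_summary.json", auto_unbox = TRUE)
cat(sprintf("kinship: %d close pairs (%d identical twin pairs), %d individuals in close pairs\n",
            s$n_close_pairs, s$n_identical_pairs,
            s$n_individuals_in_close_pairs))
close <- calls[!is.na(calls$degree) & calls$degree != "unrelated", ]
print(close[order(close$normalized_pmr), ], row.names = FALSE)
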