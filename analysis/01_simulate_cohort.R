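#!/usr/bin/env Rscript
# Step 1 — simulate the chultun-like study cohort.
#
# Generates the 64-individual pseudo-haploid cohort (100k panel SNPs,
# Beta(0.8, 0.8) ancestral frequencies, 10% missingness) whose pedigree
# plants two MZ twin pairs and nine further close-relative pairs (11 pairs,
# 16 individuals), plus per-individual X/Y/autosome coverage profiles for an
# all-male cohort at 0.1x depth. Writes EIGENSTRAT files, the coverage
# table and the ground-truth relationships under results/cohort/.

library(chultun)

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- chultun_like_cohort(n_snps = 100000L, missing_rate = 0.1, seed = seed)
write_eigenstrat(cc$matrix, file.path(out, "chultun_like"))
write.table(cc$truth$pairs[cc$truth$pairs$degree != "unrelated", ],
            file.path(out, "truth_close_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cov <- simulate_sex_coverage(
  setNames(rep("male", 64), cc$matrix$ind$label),
  mean_depth = 0.1, seed = seed)
write.table(cov, file.path(out, "coverage.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d SNPs x %d individuals, %.1f%% missing calls\n",
            nrow(cc$matrix$calls), ncol(cc$matrix$calls),
            100 * mean(is.na(cc$matrix$calls))))
cat(sprintf("planted: %d close pairs (%d identical), %d individuals\n",
            sum(cc$truth$pairs$degree != "unrelated"),
            sum(cc$truth$pairs$degree == "identical"),
            length(unique(unlist(
              cc$truth$pairs[cc$truth$pairs$degree != "unrelated",
                             c("sample_i", "sample_j")])))))
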