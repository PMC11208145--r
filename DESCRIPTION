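Package: chultun
Title: Population-Genetic and Isotopic Analysis of an Ancient Mass-Burial Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for low-coverage ancient-DNA cohorts genotyped by
    pseudo-haploid random draw on a capture SNP panel. Implements coverage-based
    genetic sexing from X/Y-to-autosome coverage ratios, pairwise-mismatch-rate
    (PMR) kinship with monozygotic-twin detection, the three-population
    locus-specific branch length (LSBL) selection scan with Hudson FST,
    outgroup f3 and f4 statistics with block-jackknife errors, HLA
    allele-frequency-shift testing with FDR control, a permutation-calibrated
    non-overlapping-association score for HLA locus pairs, and bone-collagen
    stable-isotope quality control and dietary-similarity tests. Includes a
    synthetic-cohort generator (pedigrees with twins, coverage profiles, HLA
    tables, three-population frequency sets) with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
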