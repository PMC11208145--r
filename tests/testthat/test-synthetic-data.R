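test_that("allele frequency generator matches its Beta prior", {
  # near-degenerate symmetric prior concentrates at 0.5
  p <- generate_allele_frequencies(4, alpha = 1e6, beta = 1e6, seed = 1)
  expect_true(all(abs(p - 0.5) < 0.01))

  p <- generate_allele_frequencies(1e5, alpha = 0.8, beta = 0.8, seed = 1)
  expect_true(all(p > 0 & p < 1))
  se <- sqrt(var(p) / length(p))
  expect_lt(abs(mean(p) - 0.5), 3 * se)

  expect_identical(generate_allele_frequencies(100, seed = 7),
                   generate_allele_frequencies(100, seed = 7))
  expect_error(generate_allele_frequencies(0), "n_snps")
  expect_error(generate_allele_frequencies(10, alpha = -1), "positive")
})

test_that("pedigree cohorts obey Mendelian transmission and MZ identity", {
  ped <- pedigree_spec(
    founders = c("F1", "F2"),
    relations = data.frame(child = c("C1", "C2"),
                           parent1 = c("F1", "F1"), parent2 = c("F2", "F2"),
                           stringsAsFactors = FALSE),
    mz_twin_pairs = list(c("C1", "T1")))
  cfg <- cohort_config(n_snps = 1e5, pedigree = ped, seed = 3)
  out <- generate_pedigree_cohort(cfg)
  G <- out$genotypes

  # MZ twins carry identical diploid genomes
  expect_identical(G[, "C1"], G[, "T1"])

  # child shares at least one allele with each parent at every site
  incompatible <- (G[, "C1"] == 0 & G[, "F1"] == 2) |
    (G[, "C1"] == 2 & G[, "F1"] == 0)
  expect_equal(sum(incompatible), 0)

  # full sibs share 0 alleles IBD at ~1/4 of sites: check via the truth table
  tr <- out$truth$pairs
  deg <- function(a, b) tr$degree[(tr$sample_i == a & tr$sample_j == b) |
                                    (tr$sample_i == b & tr$sample_j == a)]
  expect_equal(deg("C1", "C2"), "first")
  expect_equal(deg("C1", "T1"), "identical")
  expect_equal(deg("T1", "C2"), "first")
  expect_equal(deg("F1", "C1"), "first")
  expect_equal(deg("F1", "F2"), "unrelated")
})

test_that("full-sib IBD sharing matches the (1/4, 1/2, 1/4) distribution", {
  # at freq 0.5 everywhere, sibs sharing 0 alleles IBD are detectable as
  # opposite homozygotes with probability 1/4 * 2 * (1/4 * 1/4) ... instead
  # track IBD directly: P(0 IBD) = 1/4; estimate from opposite homozygotes,
  # whose probability is P(0 IBD) * P(opposite homo | unrelated) = 1/4 * 1/8
  ped <- pedigree_spec(
    founders = c("F1", "F2"),
    relations = data.frame(child = c("S1", "S2"),
                           parent1 = "F1", parent2 = "F2",
                           stringsAsFactors = FALSE))
  m <- 1e5
  cfg <- cohort_config(n_snps = m, pedigree = ped, seed = 11)
  out <- generate_pedigree_cohort(cfg, freqs = rep(0.5, m))
  G <- out$genotypes
  opp <- mean((G[, "S1"] == 0 & G[, "S2"] == 2) |
                (G[, "S1"] == 2 & G[, "S2"] == 0))
  expected <- 0.25 * (2 * 0.5^4)   # P(no IBD) * P(opposite homozygotes)
  se <- sqrt(expected * (1 - expected) / m)
  expect_lt(abs(opp - expected), 3 * se)
})

test_that("pedigree validation rejects unknown parents and bad twins", {
  expect_error(pedigree_spec(
    founders = "F1",
    relations = data.frame(child = "C1", parent1 = "F1", parent2 = "NOPE",
                           stringsAsFactors = FALSE)), "pedigree error")
  expect_error(pedigree_spec(founders = c("A", "A")), "unique")
  expect_error(pedigree_spec(founders = "A", mz_twin_pairs = list("A")),
               "twin")
})

test_that("pseudo-haploidization draws fair alleles and drops sites at the missing rate", {
  m <- 1e5
  dip <- matrix(c(rep(0L, m), rep(2L, m), rep(1L, m)), ncol = 3,
                dimnames = list(NULL, c("hom0", "hom2", "het")))
  gm <- pseudo_haploidize(dip, missing_rate = 0.1, seed = 5)
  calls <- gm$calls
  expect_true(all(calls[, "hom0"] %in% c(0L, NA)))
  expect_true(all(calls[, "hom2"] %in% c(1L, NA)))
  het <- calls[, "het"]
  frac_alt <- mean(het, na.rm = TRUE)
  n_het <- sum(!is.na(het))
  expect_lt(abs(frac_alt - 0.5), 3 * sqrt(0.25 / n_het))
  miss <- mean(is.na(calls))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / length(calls)))
  expect_error(pseudo_haploidize(dip, missing_rate = 1), "missing_rate")
  expect_error(pseudo_haploidize(matrix(3L, 1, 1)), "0, 1, 2")
})

test_that("sex coverage simulation matches the karyotype model", {
  cov_m <- simulate_sex_coverage(rep("male", 200), mean_depth = 0.2, seed = 1)
  r_m <- compute_rates(cov_m)
  expect_lt(abs(mean(r_m$x_rate) - 0.5), 0.01)
  expect_lt(abs(mean(r_m$y_rate) - 0.5), 0.01)
  cov_f <- simulate_sex_coverage(rep("female", 200), mean_depth = 0.2, seed = 1)
  r_f <- compute_rates(cov_f)
  expect_lt(abs(mean(r_f$x_rate) - 1.0), 0.01)
  expect_lt(abs(mean(r_f$y_rate) - 0.01), 0.005)
  expect_identical(simulate_sex_coverage(c(a = "male"), seed = 9),
                   simulate_sex_coverage(c(a = "male"), seed = 9))
  expect_error(simulate_sex_coverage("other"), "male")
  expect_error(simulate_sex_coverage("male", mean_depth = 0), "positive")
})

test_that("HLA cohort simulation plants the requested frequency shift", {
  pool <- hla_test_pool()
  # null: no shift, pools identical
  sim0 <- simulate_hla_cohorts(pool, numeric(), n1 = 50, n2 = 50, seed = 1)
  expect_equal(sim0$pool2$freq, pool$freq)

  # two fully distinct haplotypes: every draw is one of the two
  pool2 <- data.frame(A = c("A*01:01", "A*02:01"),
                      B = c("B*07:02", "B*08:01"),
                      freq = c(0.5, 0.5), stringsAsFactors = FALSE)
  sim2 <- simulate_hla_cohorts(pool2, numeric(), n1 = 30, n2 = 30, seed = 2)
  haps <- sim2$haplotypes[[1]]
  a_alleles <- haps$allele[haps$locus == "A"]
  expect_true(all(a_alleles %in% pool2$A))

  # planted +0.25 delta observed within 3 binomial SEs
  delta <- 0.25
  sim <- simulate_hla_cohorts(pool, c("DRB1=DRB1*04:07" = delta),
                              n1 = 50, n2 = 500, seed = 3)
  tab <- allele_frequencies(sim$genotypes[[2]], "c2")
  f_obs <- tab$freq[tab$allele == "DRB1*04:07"]
  f_exp <- 0.234 + delta
  expect_lt(abs(f_obs - f_exp), 3 * sqrt(f_exp * (1 - f_exp) / 1000))

  expect_error(simulate_hla_cohorts(pool, c("DRB1=DRB1*04:07" = 0.9),
                                    n1 = 5, n2 = 5),
               "negative|normalizable")
})

test_that("three-population frequency sets are reproducible and respect the null", {
  base <- generate_allele_frequencies(2000, seed = 21)
  s1 <- simulate_selection_shift(base, 1:10, shift = 0.4, seed = 5)
  s2 <- simulate_selection_shift(base, 1:10, shift = 0.4, seed = 5)
  expect_identical(s1, s2)
  expect_error(simulate_selection_shift(base, 5000L), "out of range")
  # null scenario: populations exchangeable, planted set hits the tail at
  # chance level (binomial(100, 0.005) has mean 0.5)
  null <- simulate_selection_shift(base, integer(), shift = 0, seed = 6)
  scan <- lsbl_scan(null$A, null$B, null$C)
  arbitrary <- 1:100
  hits <- sum(scan$tail_A[arbitrary] != "none", na.rm = TRUE)
  expect_lte(hits, 5)  # P(Binom(100, ~0.005) > 5) << 0.001
})

test_that("generated heterozygosity matches the Beta prior expectation", {
  ped <- pedigree_spec(founders = sprintf("F%d", 1:50))
  m <- 2e4
  cfg <- cohort_config(n_snps = m, pedigree = ped, seed = 13)
  out <- generate_pedigree_cohort(cfg)
  het <- mean(out$genotypes == 1L)
  # E[2p(1-p)] under Beta(a,b): 2ab/((a+b)(a+b+1))
  expected <- 2 * 0.8 * 0.8 / (1.6 * 2.6)
  expect_lt(abs(het - expected), 0.01)
})

test_that("the chultun-like pedigree encodes the published relatedness structure", {
  ped <- chultun_like_pedigree()
  expect_length(ped$cohort, 64)
  cfg <- cohort_config(n_snps = 100, pedigree = ped, seed = 1)
  out <- generate_pedigree_cohort(cfg)
  tr <- out$truth$pairs
  close <- tr[tr$degree %in% c("identical", "first", "second"), ]
  expect_equal(nrow(close), 11)
  expect_equal(sum(close$degree == "identical"), 2)
  expect_equal(length(unique(c(close$sample_i, close$sample_j))), 16)
  expect_setequal(unique(out$truth$sex), "male")
})
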