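test_that("allele frequencies count two alleles per typed individual", {
  geno <- data.frame(sample = c("s1", "s2"), locus = "DRB1",
                     allele1 = "DRB1*04:07", allele2 = "DRB1*04:07",
                     stringsAsFactors = FALSE)
  tab <- allele_frequencies(geno, "c")
  expect_equal(tab$freq, 1)
  expect_equal(tab$total_alleles, 4)

  geno2 <- data.frame(sample = c("s1", "s2"), locus = "A",
                      allele1 = c("A*01:01", "A*02:01"),
                      allele2 = c("A*02:01", "A*02:01"),
                      stringsAsFactors = FALSE)
  tab2 <- allele_frequencies(geno2, "c")
  expect_equal(sort(tab2$freq), c(0.25, 0.75))

  empty <- geno[0, ]
  expect_equal(nrow(allele_frequencies(empty, "c")), 0)

  bad <- transform(geno, allele2 = "whoops")
  expect_error(allele_frequencies(bad, "c"), "malformed")
})

test_that("Fisher exact p equals hypergeometric enumeration for all margins up to 30", {
  for (t1 in c(4, 9, 17, 30)) for (t2 in c(5, 12, 30)) {
    for (c1 in seq(0, t1, by = 3)) for (c2 in seq(0, t2, by = 4)) {
      got <- fisher_exact_2x2(c1, t1, c2, t2)$p
      expect_equal(got, fisher_p_enum(c1, t1, c2, t2), tolerance = 1e-10,
                   info = sprintf("table %d/%d vs %d/%d", c1, t1, c2, t2))
    }
  }
})

test_that("Fisher exact test edge cases and symmetry", {
  expect_equal(fisher_exact_2x2(5, 10, 5, 10)$p, 1)
  expect_equal(fisher_exact_2x2(10, 10, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(3, 12, 7, 19)$p,
               fisher_exact_2x2(7, 19, 3, 12)$p)
  expect_error(fisher_exact_2x2(1, 0, 1, 10), "totals")
})

test_that("BH adjustment equals the literal step-up on random p-vectors", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(23)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, bh_stepup(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p ranks
    expect_true(all(q >= p))
  }
})

test_that("cohort comparison flags planted shifts and nothing under the null", {
  pool <- hla_test_pool()
  sim0 <- simulate_hla_cohorts(pool, numeric(), n1 = 60, n2 = 60, seed = 31)
  t1 <- allele_frequencies(sim0$genotypes[[1]], "c1")
  t2 <- allele_frequencies(sim0$genotypes[[2]], "c2")
  res0 <- compare_cohorts(t1, t2)
  expect_true(all(!res0$significant) || sum(res0$significant) <= 1)

  # identical tables give p = 1 everywhere
  res_same <- compare_cohorts(t1, t1)
  expect_true(all(res_same$p_raw > 1 - 1e-6))
  expect_equal(sum(res_same$significant), 0)

  detected <- vapply(1:10, function(s) {
    sim <- simulate_hla_cohorts(pool, c("DRB1=DRB1*04:07" = 0.4627 - 0.2340),
                                n1 = 47, n2 = 67, seed = 400 + s)
    ta <- allele_frequencies(sim$genotypes[[1]], "c1")
    tb <- allele_frequencies(sim$genotypes[[2]], "c2")
    res <- compare_cohorts(ta, tb)
    hit <- res$allele == "DRB1*04:07" & res$significant &
      res$direction == "increase"
    any(hit)
  }, NA)
  expect_gte(mean(detected), 0.8)
})

test_that("non-overlap score hits its contract values", {
  perfect <- matrix(c(50, 0, 0, 50), 2, 2,
                    dimnames = list(c("A1", "A2"), c("B1", "B2")))
  expect_equal(f_adj_star(perfect), 1)

  indep <- matrix(25, 2, 2, dimnames = list(c("A1", "A2"), c("B1", "B2")))
  expect_equal(f_adj_star(indep), 0)

  degenerate <- matrix(c(10, 20), 1, 2,
                       dimnames = list("A1", c("B1", "B2")))
  expect_true(is.na(f_adj_star(degenerate)))
  expect_match(attr(f_adj_star(degenerate), "reason"), "degenerate")
})

test_that("non-overlap score matches a brute-force recomputation on a 3x3 table", {
  tab <- matrix(c(12, 3, 0,
                  2, 20, 1,
                  0, 4, 8), 3, 3, byrow = TRUE,
                dimnames = list(paste0("A", 1:3), paste0("B", 1:3)))
  # independent literal recomputation of the documented formula
  directional <- function(tb) {
    w <- rowSums(tb) / sum(tb)
    num <- 0; den <- 0
    for (a in 1:(nrow(tb) - 1)) for (b in (a + 1):nrow(tb)) {
      qa <- tb[a, ] / sum(tb[a, ]); qb <- tb[b, ] / sum(tb[b, ])
      num <- num + w[a] * w[b] * sum(pmin(qa, qb))
      den <- den + w[a] * w[b]
    }
    1 - num / den
  }
  oracle <- unname((directional(tab) + directional(t(tab))) / 2)
  expect_equal(f_adj_star(tab), oracle)

  # invariant to allele relabeling and locus swap
  perm <- tab[c(2, 3, 1), c(3, 1, 2)]
  expect_equal(f_adj_star(perm), f_adj_star(tab))
  expect_equal(f_adj_star(t(tab)), f_adj_star(tab))
})

test_that("permutations preserve both allele margins and are reproducible", {
  tab <- matrix(c(30, 5, 2, 25), 2, 2,
                dimnames = list(c("A1", "A2"), c("B1", "B2")))
  r1 <- permutation_null(tab, n_perm = 50, seed = 7)
  r2 <- permutation_null(tab, n_perm = 50, seed = 7)
  expect_identical(r1$sd_units, r2$sd_units)
  expect_gt(r1$sd_units, 0)   # strong non-overlap exceeds the null mean

  # margin preservation: permuting cannot change either margin by design;
  # verify via a table whose null scores all come from margin-true tables
  tab3 <- matrix(c(10, 0, 0, 0, 10, 0, 0, 0, 10), 3, 3,
                 dimnames = list(paste0("A", 1:3), paste0("B", 1:3)))
  r3 <- permutation_null(tab3, n_perm = 20, seed = 1)
  expect_equal(r3$f_adj_star, 1)
  expect_true(r3$sd_units > 0)
})

test_that("the permutation null is calibrated under independence", {
  # haplotype pairs drawn independently: |sd units| < 3 in almost all seeds
  n_extreme <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(9000 + s)
    a1 <- sample(c("A1", "A2"), 120, TRUE)
    a2 <- sample(c("B1", "B2", "B3"), 120, TRUE)
    tab <- as.matrix(table(a1, a2))
    r <- permutation_null(tab, n_perm = 200, seed = s)
    if (!is.na(r$sd_units) && abs(r$sd_units) >= 3) n_extreme <- n_extreme + 1
  }
  expect_lte(n_extreme, 1)
})

test_that("haplotype pair tables are built from phased haplotype lists", {
  haps <- data.frame(
    sample = rep(c("s1", "s2"), each = 4),
    haplotype_index = rep(c(1, 1, 2, 2), 2),
    locus = rep(c("DRB1", "DQB1"), 4),
    allele = c("DRB1*04:07", "DQB1*03:02", "DRB1*14:02", "DQB1*03:01",
               "DRB1*04:07", "DQB1*03:02", "DRB1*04:07", "DQB1*03:02"),
    stringsAsFactors = FALSE)
  tab <- haplotype_pair_table(haps, "DRB1", "DQB1")
  expect_equal(tab["DRB1*04:07", "DQB1*03:02"], 3)
  expect_equal(tab["DRB1*14:02", "DQB1*03:01"], 1)
  expect_equal(sum(tab), 4)
})
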