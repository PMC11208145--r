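#' Draw ancestral allele frequencies from a Beta prior
#'
#' Capture SNP panels are ascertained for common variation, giving a U-shaped
#' site-frequency spectrum; a Beta(0.8, 0.8) prior reproduces that shape and
#' is the package default. Boundary draws (exactly 0 or 1) are resampled so
#' every site is polymorphic in the ancestral pool.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param alpha,beta shape parameters of the Beta prior (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `n_snps`, strictly inside (0, 1).
#' @export
generate_allele_frequencies <- function(n_snps, alpha = 0.8, beta = 0.8,
                                        seed = NULL) {
  if (!is.numeric(n_snps) || length(n_snps) != 1L || n_snps < 1)
    stop_invalid("n_snps must be a single integer >= 1")
  if (alpha <= 0 || beta <= 0)
    stop_invalid("Beta shape parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(n_snps, alpha, beta)
  bad <- which(p <= 0 | p >= 1)
  while (length(bad) > 0L) {
    p[bad] <- rbeta(length(bad), alpha, beta)
    bad <- bad[p[bad] <= 0 | p[bad] >= 1]
  }
  p
}

#' Specify a pedigree with optional monozygotic twin pairs
#'
#' @param founders character vector of founder labels (unrelated individuals
#'   drawn under Hardy-Weinberg from the ancestral frequencies).
#' @param relations data frame with columns `child`, `parent1`, `parent2`;
#'   each parent must be a founder or an earlier child (the relation graph is
#'   checked to be acyclic).
#' @param mz_twin_pairs list of length-2 character vectors; the second member
#'   of each pair receives a copy of the first member's diploid genome. A twin
#'   copy must not itself appear as a child in `relations`.
#' @param cohort optional character vector naming the individuals returned by
#'   [generate_pedigree_cohort()] (e.g. excluding latent parents); defaults to
#'   every individual in the pedigree.
#' @return an object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(founders, relations = NULL, mz_twin_pairs = list(),
                          cohort = NULL) {
  relations <- relations %||%
    data.frame(child = character(), parent1 = character(),
               parent2 = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent1", "parent2") %in% names(relations)))
  twins <- lapply(mz_twin_pairs, as.character)
  if (any(vapply(twins, length, 1L) != 2L))
    stop_invalid("each MZ twin pair must have exactly two labels")
  copies <- vapply(twins, `[`, "", 2L)
  known <- c(founders, relations$child)
  if (anyDuplicated(c(known, copies)))
    stop_invalid("pedigree labels must be unique")
  for (i in seq_len(nrow(relations))) {
    avail <- c(founders, relations$child[seq_len(i - 1L)])
    if (!all(c(relations$parent1[i], relations$parent2[i]) %in% avail))
      stop_invalid("pedigree error: parents of '%s' are not founders or earlier children",
                   relations$child[i])
  }
  all_ids <- c(known, copies)
  structure(list(founders = founders, relations = relations,
                 mz_twin_pairs = twins,
                 cohort = cohort %||% all_ids, all_ids = all_ids),
            class = "pedigree_spec")
}

#' Configuration for a synthetic pseudo-haploid cohort
#'
#' @param n_snps number of SNPs on the simulated panel.
#' @param pedigree a [pedigree_spec()].
#' @param freq_prior_alpha,freq_prior_beta Beta prior shapes for ancestral
#'   allele frequencies.
#' @param missing_rate per-call probability of a missing genotype in `[0, 1)`.
#' @param seed integer RNG seed; the same configuration and seed give
#'   bit-identical output.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_snps, pedigree, freq_prior_alpha = 0.8,
                          freq_prior_beta = 0.8, missing_rate = 0,
                          seed = 1L) {
  if (n_snps < 1) stop_invalid("n_snps must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must be in [0, 1)")
  if (!inherits(pedigree, "pedigree_spec"))
    stop_invalid("pedigree must be a pedigree_spec")
  structure(list(n_snps = as.integer(n_snps), pedigree = pedigree,
                 freq_prior_alpha = freq_prior_alpha,
                 freq_prior_beta = freq_prior_beta,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

# Kinship coefficients by the standard pedigree recursion; MZ copies share
# their template's genome, so phi(copy, x) = phi(template, x) and
# phi(copy, template) = phi(template, template).
pedigree_kinship <- function(ped) {
  ids <- c(ped$founders, ped$relations$child)
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  parents <- matrix(NA_integer_, n, 2L)
  for (i in seq_len(nrow(ped$relations))) {
    k <- idx[[ped$relations$child[i]]]
    parents[k, ] <- c(idx[[ped$relations$parent1[i]]],
                      idx[[ped$relations$parent2[i]]])
  }
  for (i in seq_len(n)) {
    if (is.na(parents[i, 1L])) {
      phi[i, i] <- 0.5
    } else {
      m <- parents[i, 1L]; f <- parents[i, 2L]
      phi[i, i] <- 0.5 * (1 + phi[m, f])
      for (j in seq_len(i - 1L)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[m, j] + phi[f, j])
      }
    }
  }
  # append MZ copies as exact duplicates of their templates
  for (tw in ped$mz_twin_pairs) {
    tmpl <- tw[1L]; cp <- tw[2L]
    row <- phi[tmpl, , drop = TRUE]
    phi <- rbind(cbind(phi, row), c(row, phi[tmpl, tmpl]))
    rownames(phi)[nrow(phi)] <- cp
    colnames(phi)[ncol(phi)] <- cp
  }
  phi
}

degree_from_kinship <- function(phi, mz_pairs) {
  ids <- rownames(phi)
  mz_key <- vapply(mz_pairs, function(tw)
    paste(sort(tw), collapse = "\r"), "")
  out <- list()
  k <- 0L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
    kin <- phi[i, j]
    deg <- if (key %in% mz_key) "identical"
           else if (kin >= 0.25 - 1e-9) "first"
           else if (kin >= 0.125 - 1e-9) "second"
           else "unrelated"
    k <- k + 1L
    out[[k]] <- data.frame(sample_i = ids[i], sample_j = ids[j],
                           kinship = kin, degree = deg,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate diploid genotypes for a pedigree cohort
#'
#' Founders are drawn under Hardy-Weinberg from the ancestral allele
#' frequencies; children receive one allele per parent by fair Mendelian
#' transmission; MZ twin copies receive their template's diploid genome
#' unchanged. The returned truth table records pairwise relationship degrees
#' (identical / first / second / unrelated) derived from pedigree kinship
#' coefficients, and declared sexes (all male by default, matching an
#' all-male burial cohort).
#'
#' @param config a [cohort_config()].
#' @param freqs optional ancestral frequency vector (length `n_snps`);
#'   generated from the Beta prior when omitted.
#' @return list with `genotypes` (n_snps x n_individuals matrix of 0/1/2,
#'   cohort individuals only), `truth` (pair degrees and per-individual sex)
#'   and `freqs`.
#' @export
generate_pedigree_cohort <- function(config, freqs = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ped <- config$pedigree
  set.seed(config$seed)
  freqs <- freqs %||% generate_allele_frequencies(
    config$n_snps, config$freq_prior_alpha, config$freq_prior_beta)
  if (length(freqs) != config$n_snps)
    stop_invalid("frequency vector length != n_snps")
  m <- config$n_snps
  # haplotypes stored as two allele columns per individual
  hap <- new.env(parent = emptyenv())
  for (f in ped$founders) {
    assign(f, cbind(rbinom(m, 1L, freqs), rbinom(m, 1L, freqs)), envir = hap)
  }
  transmit <- function(h) {
    pick <- rbinom(m, 1L, 0.5) + 1L
    h[cbind(seq_len(m), pick)]
  }
  for (i in seq_len(nrow(ped$relations))) {
    p1 <- get(ped$relations$parent1[i], envir = hap)
    p2 <- get(ped$relations$parent2[i], envir = hap)
    assign(ped$relations$child[i], cbind(transmit(p1), transmit(p2)),
           envir = hap)
  }
  for (tw in ped$mz_twin_pairs) {
    if (!exists(tw[1L], envir = hap))
      stop_invalid("pedigree error: twin template '%s' has no genotype", tw[1L])
    assign(tw[2L], get(tw[1L], envir = hap), envir = hap)
  }
  cohort <- ped$cohort
  G <- vapply(cohort, function(id) {
    h <- get(id, envir = hap)
    h[, 1L] + h[, 2L]
  }, integer(m))
  phi <- pedigree_kinship(ped)
  truth_pairs <- degree_from_kinship(phi[cohort, cohort, drop = FALSE],
                                     ped$mz_twin_pairs)
  truth <- list(pairs = truth_pairs,
                sex = setNames(rep("male", length(cohort)), cohort))
  list(genotypes = G, truth = truth, freqs = freqs)
}

# Spread SNPs over autosomes 1..22 in contiguous blocks with 1kb spacing.
default_snp_table <- function(n_snps) {
  chrom <- sort(rep_len(1:22, n_snps))
  pos <- integer(n_snps)
  for (c_ in unique(chrom)) {
    sel <- chrom == c_
    pos[sel] <- seq_len(sum(sel)) * 1000L
  }
  data.frame(id = sprintf("snp%d", seq_len(n_snps)),
             chrom = as.character(chrom), pos = pos,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Emulates pseudo-haploid random-draw genotyping: at each retained site one
#' allele is drawn uniformly from the individual's two; sites are dropped
#' independently with probability `missing_rate`.
#'
#' @param diploid n_snps x n_individuals matrix with values in `{0, 1, 2}`
#'   (alt-allele dosage); column names are individual labels.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @param snp,ind optional SNP/individual metadata tables; synthesized when
#'   omitted (autosomal positions, unknown sex).
#' @return a [genotype_matrix()] with calls in `{0, 1, NA}`.
#' @export
pseudo_haploidize <- function(diploid, missing_rate = 0, seed = NULL,
                              snp = NULL, ind = NULL) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must be in [0, 1)")
  if (!all(diploid %in% c(0L, 1L, 2L)))
    stop_invalid("diploid matrix must contain only 0, 1, 2")
  if (!is.null(seed)) set.seed(seed)
  calls <- matrix(0L, nrow(diploid), ncol(diploid),
                  dimnames = dimnames(diploid))
  calls[diploid == 2L] <- 1L
  het <- which(diploid == 1L)
  if (length(het)) calls[het] <- rbinom(length(het), 1L, 0.5)
  if (missing_rate > 0) {
    drop <- runif(length(calls)) < missing_rate
    calls[drop] <- NA_integer_
  }
  labels <- colnames(diploid) %||% sprintf("ind%d", seq_len(ncol(diploid)))
  snp <- snp %||% default_snp_table(nrow(diploid))
  ind <- ind %||% data.frame(label = labels, sex = "U", group = "cohort",
                             stringsAsFactors = FALSE)
  colnames(calls) <- labels
  genotype_matrix(calls, snp, ind)
}

#' Simulate per-class SNP coverage for genetic sexing
#'
#' Read totals per chromosome class follow the karyotype model: autosomal
#' targets at the full depth; males at half depth on X and Y; females at full
#' depth on X and at a small spurious-mapping rate on Y. Per-class totals are
#' drawn as Poisson sums over targeted sites. Default targeted-site counts
#' emulate a 1240K-style capture panel.
#'
#' @param sexes character vector of "male"/"female", one per individual;
#'   names are used as sample labels.
#' @param mean_depth mean autosomal reads per targeted site (> 0).
#' @param n_auto,n_x,n_y targeted-site counts per chromosome class.
#' @param female_y_rate spurious female Y coverage as a fraction of
#'   `mean_depth` (default 1%).
#' @param seed optional integer seed.
#' @return long-format coverage table: `sample`, `chromosome_class`
#'   (autosome/X/Y), `sites_covered`, `total_reads`.
#' @export
simulate_sex_coverage <- function(sexes, mean_depth = 0.1,
                                  n_auto = 1150000L, n_x = 49700L,
                                  n_y = 32600L, female_y_rate = 0.01,
                                  seed = NULL) {
  if (mean_depth <= 0) stop_invalid("mean_depth must be positive")
  if (!all(sexes %in% c("male", "female")))
    stop_invalid("sexes must be 'male' or 'female'")
  if (!is.null(seed)) set.seed(seed)
  labels <- names(sexes) %||% sprintf("ind%02d", seq_along(sexes))
  rows <- lapply(seq_along(sexes), function(i) {
    male <- sexes[i] == "male"
    depth_x <- if (male) mean_depth / 2 else mean_depth
    depth_y <- if (male) mean_depth / 2 else female_y_rate * mean_depth
    data.frame(
      sample = labels[i],
      chromosome_class = c("autosome", "X", "Y"),
      sites_covered = c(n_auto, n_x, n_y),
      total_reads = c(rpois(1L, n_auto * mean_depth),
                      rpois(1L, n_x * depth_x),
                      rpois(1L, n_y * depth_y)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate two HLA cohorts from a haplotype pool with planted shifts
#'
#' Cohort 1 draws haplotypes from the pool as given; cohort 2 from the pool
#' after applying per-allele frequency deltas: the delta for an allele is
#' distributed over the haplotypes carrying it in proportion to their pool
#' frequency, and the complement is renormalized so frequencies still sum
#' to 1. Each individual receives two independent haplotypes; phase is
#' retained.
#'
#' @param pool data frame with one column per HLA locus (allele names) plus a
#'   `freq` column summing to 1.
#' @param shift_spec named numeric vector of frequency deltas, names like
#'   `"DRB1=DRB1*04:07"` (locus, then allele, separated by `=`). Empty for a
#'   null comparison.
#' @param n1,n2 individuals per cohort (>= 1).
#' @param seed optional integer seed.
#' @param cohort_names labels for the two cohorts.
#' @return list with `genotypes` and `haplotypes`, each a list of two data
#'   frames in the package's HLA CSV schemas, plus `pool2` (the shifted pool).
#' @export
simulate_hla_cohorts <- function(pool, shift_spec = numeric(), n1, n2,
                                 seed = NULL,
                                 cohort_names = c("cohort1", "cohort2")) {
  loci <- setdiff(names(pool), "freq")
  if (length(loci) < 1L || is.null(pool$freq))
    stop_invalid("pool needs locus columns and a freq column")
  if (abs(sum(pool$freq) - 1) > 1e-8)
    stop_invalid("pool frequencies must sum to 1")
  if (n1 < 1 || n2 < 1) stop_invalid("cohort sizes must be >= 1")
  f2 <- pool$freq
  for (nm in names(shift_spec)) {
    parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !(parts[1L] %in% loci))
      stop_invalid("shift_spec name '%s' is not 'locus=allele'", nm)
    carrier <- pool[[parts[1L]]] == parts[2L]
    if (!any(carrier)) stop_invalid("no pool haplotype carries %s", nm)
    delta <- shift_spec[[nm]]
    f2[carrier] <- f2[carrier] + delta * f2[carrier] / sum(f2[carrier])
    f2[!carrier] <- f2[!carrier] - delta * f2[!carrier] / sum(f2[!carrier])
  }
  if (any(f2 < -1e-12) || abs(sum(f2) - 1) > 1e-8)
    stop_invalid("shifted frequencies are negative or not normalizable")
  f2 <- pmax(f2, 0); f2 <- f2 / sum(f2)
  if (!is.null(seed)) set.seed(seed)
  draw_cohort <- function(n, f, prefix) {
    hap_idx <- matrix(sample.int(nrow(pool), 2L * n, replace = TRUE,
                                 prob = f), ncol = 2L)
    samples <- sprintf("%s%03d", prefix, seq_len(n))
    geno <- do.call(rbind, lapply(loci, function(L) {
      data.frame(sample = samples, locus = L,
                 allele1 = pool[[L]][hap_idx[, 1L]],
                 allele2 = pool[[L]][hap_idx[, 2L]],
                 stringsAsFactors = FALSE)
    }))
    haps <- do.call(rbind, lapply(1:2, function(h) {
      do.call(rbind, lapply(loci, function(L) {
        data.frame(sample = samples, haplotype_index = h, locus = L,
                   allele = pool[[L]][hap_idx[, h]],
                   stringsAsFactors = FALSE)
      }))
    }))
    list(genotypes = geno[order(geno$sample, geno$locus), ],
         haplotypes = haps[order(haps$sample, haps$haplotype_index,
                                 haps$locus), ])
  }
  c1 <- draw_cohort(n1, pool$freq, substr(cohort_names[1L], 1L, 3L))
  c2 <- draw_cohort(n2, f2, substr(cohort_names[2L], 1L, 3L))
  list(genotypes = setNames(list(c1$genotypes, c2$genotypes), cohort_names),
       haplotypes = setNames(list(c1$haplotypes, c2$haplotypes), cohort_names),
       pool2 = transform(pool, freq = f2))
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate three-population frequency sets with planted selected loci
#'
#' Populations B and C drift independently from the base frequencies
#' (Gaussian noise on the logit scale); population A drifts the same way and
#' is additionally shifted by `shift` (on the frequency scale, clamped inside
#' (0, 1)) at `selected_indices` only. Observed allele counts are then
#' binomially sampled per population, emulating pseudo-haploid allele calls.
#'
#' @param base_freqs numeric vector of base allele frequencies in (0, 1).
#' @param selected_indices integer indices of planted selected loci (may be
#'   empty for a null scenario).
#' @param shift frequency shift applied to population A at selected loci.
#' @param drift_sd standard deviation of logit-scale drift (default 0.05).
#' @param n_alleles called alleles sampled per population per SNP.
#' @param seed optional integer seed.
#' @return list of three data frames (`A`, `B`, `C`) with columns `count`,
#'   `total`, `freq`, plus `truth` (the planted indices).
#' @export
simulate_selection_shift <- function(base_freqs, selected_indices = integer(),
                                     shift = 0.4, drift_sd = 0.05,
                                     n_alleles = 100L, seed = NULL) {
  if (length(selected_indices) &&
      (min(selected_indices) < 1 || max(selected_indices) > length(base_freqs)))
    stop_invalid("selected_indices out of range")
  if (!is.finite(shift)) stop_invalid("invalid shift")
  if (!is.null(seed)) set.seed(seed)
  m <- length(base_freqs)
  drift <- function() inv_logit(logit(base_freqs) + rnorm(m, 0, drift_sd))
  pA <- drift(); pB <- drift(); pC <- drift()
  eps <- 1e-6
  pA[selected_indices] <- pmin(pmax(pA[selected_indices] + shift, eps), 1 - eps)
  samp <- function(p) {
    count <- rbinom(m, n_alleles, p)
    data.frame(count = count, total = n_alleles, freq = count / n_alleles)
  }
  list(A = samp(pA), B = samp(pB), C = samp(pC),
       truth = list(selected_indices = selected_indices, shift = shift))
}

#' The packaged "chultun-like" pedigree
#'
#' A 64-individual cohort mirroring the relatedness structure recovered from
#' the mass-burial context: two MZ twin pairs; a half-sibling of one twin
#' pair plus a further half-sibling of that individual through the non-shared
#' parent; three unrelated full-sib pairs; and a four-individual half-sib
#' chain. By construction 16 individuals have at least one relative of degree
#' <= 2 and there are exactly 11 such pairs (2 of them identical); the
#' remaining 48 individuals are unrelated. Parents are latent: only the 64
#' cohort members are emitted.
#'
#' @return a [pedigree_spec()] whose cohort has 64 members `CH001..CH064`.
#' @export
chultun_like_pedigree <- function() {
  cohort <- sprintf("CH%03d", 1:64)
  parents <- sprintf("P%02d", 1:17)
  singles <- cohort[17:64]
  rel <- function(child, p1, p2) data.frame(child = child, parent1 = p1,
                                            parent2 = p2,
                                            stringsAsFactors = FALSE)
  relations <- rbind(
    rel("CH001", "P01", "P02"),                  # twin pair 1 template
    rel("CH003", "P03", "P04"),                  # twin pair 2 template
    rel("CH005", "P03", "P05"),                  # half-sib of twin pair 2
    rel("CH006", "P05", "P06"),                  # half-sib of CH005 only
    rel("CH007", "P07", "P08"), rel("CH008", "P07", "P08"),  # full sibs
    rel("CH009", "P09", "P10"), rel("CH010", "P09", "P10"),  # full sibs
    rel("CH011", "P11", "P12"), rel("CH012", "P11", "P12"),  # full sibs
    rel("CH013", "P13", "P14"),                  # half-sib chain
    rel("CH014", "P14", "P15"),
    rel("CH015", "P15", "P16"),
    rel("CH016", "P16", "P17"))
  pedigree_spec(founders = c(parents, singles), relations = relations,
                mz_twin_pairs = list(c("CH001", "CH002"), c("CH003", "CH004")),
                cohort = cohort)
}

#' Generate the full chultun-like synthetic cohort
#'
#' Convenience wrapper: the chultun-like pedigree at the study's scale
#' (64 individuals, 100,000 panel SNPs, Beta(0.8, 0.8) ancestral frequencies,
#' 10% per-call missingness), pseudo-haploidized, with the ground-truth
#' relationship table attached.
#'
#' @param n_snps panel size (default 100000).
#' @param missing_rate per-call missingness (default 0.1).
#' @param seed integer seed (default 1).
#' @return list with `matrix` (a [genotype_matrix()]) and `truth`.
#' @export
chultun_like_cohort <- function(n_snps = 100000L, missing_rate = 0.1,
                                seed = 1L) {
  ped <- chultun_like_pedigree()
  cfg <- cohort_config(n_snps = n_snps, pedigree = ped,
                       missing_rate = missing_rate, seed = seed)
  gen <- generate_pedigree_cohort(cfg)
  gm <- pseudo_haploidize(gen$genotypes, missing_rate = missing_rate)
  ind <- gm$ind
  ind$sex <- "M"
  gm$ind <- ind
  list(matrix = gm, truth = gen$truth, freqs = gen$freqs)
}
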