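---
title: "Methods: population-genetic and isotopic analysis of an ancient mass-burial cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic and isotopic analysis of an ancient mass-burial cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chultun)
```

This vignette documents the statistical models behind the package, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## The data model: pseudo-haploid calls

Low-coverage ancient DNA rarely supports diploid genotype calls. The standard
workaround, which this package takes as its canonical representation, is the
*pseudo-haploid random draw*: at each SNP of a capture panel, one sequencing
read is drawn at random and its allele recorded as a haploid call. A
genotype matrix here is therefore an n_SNPs x n_individuals matrix over
{0 = reference, 1 = alternative, NA = missing}, with SNP metadata
(chromosome, 1-based position, alleles) and individual metadata (label,
declared sex, group). EIGENSTRAT geno/snp/ind is the on-disk format;
heterozygote digits encountered in a declared pseudo-haploid dataset are set
to missing with a warning rather than rejected, because merges with diploid
reference panels do occur. Individuals retaining no more than 20,000
non-missing panel SNPs are dropped by the retention filter (strict
inequality).

## Genetic sexing from coverage ratios

With equal per-site capture efficiency, the expected per-site depth on the X
and Y chromosomes relative to autosomes is (1, 1)/2 = (0.5, 0.5) for an XY
karyotype and (1, ~0) for XX. `compute_rates()` estimates

x_rate = (X reads / X targeted sites) / (autosomal reads / autosomal sites),

and analogously for Y, i.e. normalization is by targeted-SNP count per
chromosome class, not by chromosome length in bases — coverage is only
defined at targeted sites on a capture panel. A sample is called male when
x_rate is in [0.35, 0.55] **and** y_rate is in [0.4, 0.7]. The windows are
treated as inclusive; "between" is ambiguous and boundary behaviour is
asserted in the tests. Only the male window is anchored in prior practice
for this cohort type; the female rule (x_rate >= 0.8 and y_rate <= 0.1)
follows standard usage, is configurable, and tolerates a small spurious
Y-mapping rate (default 1% of autosomal depth in the simulator) caused by
X/Y homology.

## Kinship from pairwise mismatch rates

For two individuals with pseudo-haploid calls, the pairwise mismatch rate
(PMR) is the fraction of jointly non-missing autosomal SNPs at which the
calls differ. At a SNP with alternative-allele frequency p, two unrelated
individuals under Hardy-Weinberg mismatch with probability 2p(1-p); two
draws from the *same* diploid genome (monozygotic twins, or a duplicated
sample) mismatch with probability p(1-p) — half the unrelated rate. More
generally the expected PMR scales with (1 - phi), phi the kinship
coefficient, giving expected PMR ratios of 0.5 (identical), 0.75
(first degree), 0.875 (second degree) and 1 (unrelated) after dividing by
the unrelated background.

`normalize_background()` estimates that background as the **median** PMR
over all valid pairs, as in allele-sharing kinship tools for ancient DNA.
The median is robust while related pairs are a minority of all pairs; in a
64-individual cohort with 11 related pairs they are 0.5% of the 2,016
pairs. The documented failure mode is a cohort dominated by relatives
(median no longer tracks the unrelated expectation); no guard is possible
without external information, so the assumption is stated rather than
checked. Classification bins are the midpoints of the expected ratios —
0.625, 0.8125, 0.90625 — and are configurable; the published analyses this
reconstructs report degrees without printing cutoffs, so the bins are a
reconstruction, not a transcription. Pairs with fewer than 5,000 overlapping
SNPs are reported but left unclassified. X/Y SNPs are excluded from the PMR:
in an all-male cohort the X is haploid and would deflate mismatch rates
asymmetrically.

## The LSBL selection scan

The locus-specific branch length decomposes three pairwise distances among
populations A, B, C into per-population branches:

x = (d_AB + d_AC - d_BC)/2,  y = (d_AB + d_BC - d_AC)/2,
z = (d_AC + d_BC - d_AB)/2,

so x + y + z = (d_AB + d_BC + d_AC)/2 exactly (asserted to machine
precision). A large x flags an allele-frequency shift specific to A. The
distances are per-SNP Hudson FST estimates with sample-size correction —
chosen because the estimator is robust to unequal sample sizes and requires
no variance-component fitting; no specific estimator is canonical for LSBL.
Negative per-SNP estimates (expected when true differentiation is ~0, since
the correction removes sampling bias) are clipped at 0 before decomposition,
with raw values retained in the output: negative distances make branch
lengths uninterpretable.

Filters mirror standard selection-scan practice: autosomes only, pooled
MAF >= 0.01, individuals with more than 97% missing data removed, and
plink-style LD pruning (`--indep-pairwise 200 25 0.4` semantics) *before*
the scan — the conventional order, and the one implied when pruning is
listed among the QC steps. r-squared on pseudo-haploid data is the squared
correlation of the 0/1 call vectors over jointly non-missing individuals;
no diploid dosage or phase exists to do better. The drop rule (lower MAF
first, ties drop the later position) makes pruning deterministic and
idempotent, which the tests verify against a brute-force oracle.

Outlier tails are empirical per branch: the threshold is the k-th largest
value with k = floor(n * tail), ties at the threshold all included, tails
nested (top 0.1% inside top 0.5%).

## f3 and f4 statistics

Outgroup f3(O; A, B) = mean over SNPs of (p_O - p_A)(p_O - p_B) measures
shared drift of A and B since divergence from outgroup O; f4(A, B; C, D) =
mean of (p_A - p_B)(p_C - p_D) tests treeness and is antisymmetric in each
pair. Standard errors are delete-one block jackknifes over contiguous
SNP-count blocks (default 500 SNPs). SNP-count blocks rather than
centimorgan blocks are a deliberate simplification: the synthetic data have
no genetic map, and the estimate itself is invariant to the partition (it
is always the plain mean; only the SE depends on blocks). Sites missing in
any involved population are dropped per statistic. No heterozygosity
correction is applied to f3 by default: outgroup-f3 *rankings* against a
fixed (O, A), the use case here, are unaffected by a shared offset; a flag
can be added where absolute values matter.

## HLA frequency shifts and non-overlapping associations

Allele frequencies are counted per locus with two alleles per typed
individual; untyped individuals drop out of that locus's denominator.
Between-cohort shifts use two-sided Fisher exact tests (minimum-likelihood
definition, verified against full hypergeometric enumeration in the tests)
with Benjamini-Hochberg FDR control. The BH family pools all alleles across
all loci into one family — the more conservative reading of "adjusted for
several comparisons" — with per-locus families behind a flag.

The non-overlap score ranks locus pairs by how much the alleles at one
locus associate with *disjoint* sets of alleles at the other — the
predicted signature of pathogen-driven selection maintaining allele-specific
associations. The published formula for this metric lives in external work
not reproduced here, so the package implements a documented
operationalization behind a pluggable interface: for each allele a at locus
1 with margin frequency w_a, its association profile is the conditional
distribution q_a over alleles at locus 2; the score is

f*_adj = 1 - (sum over pairs a != a' of w_a w_a' * overlap(q_a, q_a')) /
             (sum of w_a w_a'),

overlap(q, q') = sum of elementwise minima, symmetrized by averaging both
locus orientations. Complete non-overlap gives 1 (maximal for the margins);
under exact independence all profiles coincide and the score is 0 in the
large-sample limit. The primary deliverable, fully specified by the study
design, is the **permutation calibration**: the haplotype list has its
locus-2 allele labels permuted (both margins preserved exactly), the score
is recomputed for each of 5,000 permutations, and the observed score is
reported as (observed - null mean)/null SD. Any monotone non-overlap
statistic can be plugged into this wrapper; the SD-unit scale is what the
heatmap-style outputs rank. Degenerate tables (one allele at a locus) are
reported as undefined rather than scored.

## Isotope quality control and dietary similarity

Bone-collagen records pass QC when collagen yield exceeds 1% by weight
(strict) and the atomic C:N ratio lies in 2.9-3.6 (inclusive); failures
carry a reason code and records with missing fields are unevaluable.
Summaries (n, min, max, mean, sample SD) cover QC-passing records only.

Dietary similarity of relatives is formalized as the mean pairwise
Euclidean distance in the (delta13C, delta15N) plane over close pairs
(degree <= 2), with equal axis weights — both axes carry dietary signal at
comparable per-mil scales, and weights are configurable. The null permutes
sample labels on the isotope records; the one-sided, add-one-corrected
p-value counts permutations at or below the observed distance. Note a
boundary subtlety: when some records are exactly tied (e.g. two identical
diets), permutations that re-place the tied records on a related pair also
attain the observed minimum, so the attainable p floor is set by the tie
probability, not by 1/(n_perm + 1).

## The synthetic-cohort generator

The generator exists so every stage is testable with known ground truth and
no external data. It emulates:

- **Ascertained panel frequencies**: ancestral allele frequencies from
  Beta(0.8, 0.8) — a U-shaped spectrum resembling SNP-array ascertainment;
  boundary draws are resampled so sites are polymorphic.
- **Pedigrees with exact IBD structure**: founders under Hardy-Weinberg,
  children by fair Mendelian transmission of one allele per parent, MZ twins
  as literal genome copies. Half-sib relationships arise from an explicit
  shared parent, not a kinship-coefficient shortcut, so IBD structure is
  exact. Truth degrees come from pedigree kinship recursion.
- **Pseudo-haploid sampling and missingness**: fair allele draw per site,
  independent per-call missingness (default 10%).
- **Sex-specific coverage**: per-class read totals as Poisson sums at
  1240K-like targeted-site counts (1,150,000 autosomal / 49,700 X /
  32,600 Y), males at half depth on X and Y, females with a 1% spurious
  Y rate.
- **HLA cohorts**: two-locus phased haplotype pools with planted per-allele
  frequency deltas, two haplotypes per individual.
- **Three-population frequency sets**: logit-scale Gaussian drift
  (default SD 0.05) from a shared base, a frequency shift (+0.4 by default)
  planted in population A at chosen loci, binomial allele-count sampling
  (default 100 called alleles per population).

It does **not** emulate: linkage disequilibrium from a coalescent process
(SNPs are independent given the pedigree, so LD-pruning behaviour on real
data is only exercised structurally), post-mortem damage, contamination, or
sequence reads. Passing tests therefore demonstrate the statistics recover
planted truth under the stated sampling models — not robustness to damage
or contamination, which upstream processing must handle.

The packaged "chultun-like" pedigree fixes the study-scale conditions: 64
individuals, 100,000 SNPs, 10% missingness, two MZ twin pairs, one
half-sibling of a twin pair plus a further half-sibling of that individual
through the other parent, three unrelated full-sib pairs and a
four-individual half-sib chain — 11 close pairs over 16 individuals, with
the remaining 48 unrelated. The published relatedness graph does not
uniquely determine the pedigree behind its chained pairs; this
configuration is the one consistent with exactly 11 pairwise relationships
of degree <= 2 (a full sibling of the twins in place of the half-sibling
would make the fourth individual in that component related to the twins as
well, yielding 13 pairs).

## Numerical and scale choices

- Planted selected loci in the scan fixtures are drawn from intermediate
  base frequencies (0.1-0.5): selection acts on standing variation with
  room to rise, and near-fixed sites yield undefined FST in both
  populations (in real scans such sites fall to the MAF filter).
- Problem sizes in the test-suite: 100,000 SNPs for full-scale kinship
  recovery (PMR expectations concentrate to ~0.005 SD at 81,000
  overlapping sites, far inside the 0.03 assertion tolerance and the
  ~0.06 half-width of the classification bins); 10,000 SNPs x 3
  populations for scan recovery; 200-500 permutations per seed for null
  calibration, 100 seeds. These sizes make every property sharp while the
  whole suite stays desk-scale.
- Determinism: every generator and permutation routine takes an explicit
  seed; equal configuration and seed give bit-identical output, asserted in
  tests.
- Degenerate inputs: zero-SNP matrices round-trip through EIGENSTRAT;
  zero-background PMR cohorts, all-tied outlier distributions, degenerate
  haplotype tables and zero-SD permutation nulls all produce explicit
  errors, warnings or NA-with-diagnosis rather than silent numbers.

## Known limitations

- The PMR background requires >= 3 valid pairs and honest unrelated
  majority; tiny cohorts or family-only cohorts need an external background.
- LD pruning is O(window^2) per window in plain R; adequate for capture
  panels at these scales, not optimized for whole-genome density.
- The non-overlap score is an operationalization; rankings in SD units are
  comparable within this package but not numerically against published
  scores computed with the original formula.
- f-statistics use SNP-count jackknife blocks; with real genetic maps,
  centimorgan blocks would be preferable.
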