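---
title: "Models and methods behind reefshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reefshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reefshift` tests whether the relative frequencies of genetic source
lineages on restored oyster reefs shift non-randomly between two
censuses separated by heavy mortality. This vignette explains the models
the package implements, the tunable parameters and their defaults, the
design decisions taken where several defensible choices existed, and
what the synthetic-data tests do and do not establish about field data.

## 1. The synthetic restoration experiment

Every inferential routine in the package is exercised against a
generator that emulates a blocked restoration experiment with known
truth.

**Source divergence.** `simulate_sources()` draws, for each locus, an
ancestral allele frequency $p \sim \mathrm{Uniform}(0.1, 0.9)$ and then
per-source frequencies from the Balding–Nichols distribution
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, whose
mean is $p$ and variance $F\,p(1-p)$. The divergence parameter $F$
directly targets the realized multilocus Weir–Cockerham $F_{ST}$ between
sources; the default $F = 0.08$ sits at the scale of differentiation
observed among commercial oyster hatchery lineages (pairwise estimates
of roughly 0.05–0.08). Balding–Nichols was chosen over demographic
simulation because the only property the tests require is a controlled,
recoverable level of differentiation.

**Reefs, blocks and families.** `simulate_cohort()` builds 16 reefs in
4 spatial blocks. One reef per block is seeded from a single source and
the other twelve are even four-source mixtures, so exactly twelve reefs
are "mixed" — the analysis set. Each reef holds a living population of
96 oysters (`pop_per_reef`), three times the census-1 sample size.
Within a source, individuals belong to full-sib families (20 families
per source by default): each family has one simulated parent pair and
offspring genotypes follow Mendelian transmission, which produces the
elevated within-lineage relatedness expected of hatchery-bred cohorts.

**Destructive censuses.** `apply_mortality()` first draws the census-1
sample (32 per reef) and removes it — census sampling of oysters is
destructive, so resampled individuals can never reappear — then applies
Bernoulli survival to the remaining population and draws the census-2
sample from the survivors, truncated into 8–32 per reef. The two census
samples are therefore disjoint draws from the same reef, and under equal
survival the census labels are exchangeable within a reef. This is the
property that makes the within-reef permutation tests exact; a generator
that nests the census-2 sample inside census 1 (the same individuals
re-counted) breaks exchangeability and makes those tests severely
conservative, which is why the package models the destructive protocol
explicitly. The population size 96 is not critical: any population large
enough to support disjoint samples of 32 and 8–32 behaves equivalently
for the analyses; 96 keeps simulation cost low while letting the
census-2 sample reach its upper truncation bound under moderate
survival.

**Survival defaults.** The default per-cluster survival vector
$(0.5, 0.5, 0.75, 0.25)$ encodes two neutral lineages, one favoured and
one disfavoured — the qualitative pattern of one increasing, one
declining and two stable lineages. These are generator choices, not
field estimates.

**Traits and parasites.** `simulate_traits()` draws size and mass
traits from lognormal distributions with cluster-specific means (moment
matched from a mean and coefficient of variation), computes condition
index as $100 \times$ dry tissue mass / dry shell mass from the
simulated masses, and draws parasite presence per individual as
Bernoulli at cluster-specific prevalence, with intensities (a log-scale
load for *Perkinsus marinus*, a beta-distributed shell-area proportion
for mud blister worm) only for infected individuals. Default
prevalences anchor to field-scale values (84.67% for *P. marinus*,
44.98% for mud blister worm). Parasites are assessed at census 1 only,
as in the protocol the generator emulates.

**Missingness.** `apply_missingness()` masks calls independently at
batch-specific rates (default 2% for the census-1 batch, 8% for the
lower-coverage census-2 batch), optionally jittered per locus. This
reproduces the batch structure that motivates the per-batch missingness
screens in the filtering cascade.

## 2. Filtering

`iterative_filter()` runs an ordered cascade, each step on the previous
step's output, and records a chained report. The default mirrors an
iterative ddRAD filtering protocol: a base locus screen (MAC ≥ 3, call
rate > 0.5), a permissive individual screen (missingness ≤ 0.815,
designed to drop failed libraries without penalizing whole low-coverage
batches), a strict locus set (call rate > 0.9, MAF > 0.01, per-batch
missing rate < 0.2), a strict individual screen (≤ 0.16), and
sliding-window LD pruning (50 variants, step 5, removing one member of
every pair with $r^2 > 0.5$). Thresholds written "greater than" are
strict inequalities. Base-quality and depth filters belong to the
variant-calling pipeline upstream of this package's entry point and are
recorded, not re-applied.

The LD removal rule is deterministic: the member with the lower call
rate is dropped, ties by lower MAF, then by later genomic position. The
external tools that perform this step do not document a single rule;
ours favours better-typed loci and makes runs reproducible. Windows
never span chromosomes. Note that a pair with $r^2 = 1$ twice over
(A with B, B with C) forces $r^2(A, C) = 1$ as well, so "chains" of
perfectly correlated loci always collapse to a single retained locus.

## 3. Cluster assignment

`pca_scores()` mean-imputes missing dosages per locus (twice the allele
frequency — the imputation that leaves the locus mean unchanged),
centres, and takes the top 100 axes. Axes are oriented so the loading of
largest magnitude is positive, removing the sign indeterminacy of the
SVD.

`find_clusters()` runs k-means for $K = 1..10$, 25 replicates per $K$,
10 random starts per replicate, and scores each replicate with
$\mathrm{BIC}(K) = n\ln(\mathrm{WSS}/n) + K\ln n$. This BIC form is the
standard spherical-Gaussian k-means criterion; any monotone-equivalent
variant gives the same elbow. `select_k()` applies the Evanno-style
statistic $\Delta(K) = |\,\overline{\mathrm{BIC}}(K{+}1) -
2\overline{\mathrm{BIC}}(K) + \overline{\mathrm{BIC}}(K{-}1)\,| /
\mathrm{sd}\,\mathrm{BIC}(K)$ over interior $K$. One numerical guard
matters: on cleanly separated data every k-means replicate can converge
to the same optimum, collapsing the replicate standard deviation to
zero exactly where the elbow is sharpest. The scale is therefore floored
at $10^{-6}$ times the BIC range, so that with degenerate replicate
noise the statistic reduces to raw second-difference elbow detection;
with real replicate noise the floor is never active. The number of
k-means starts also matters here — with too few starts, occasional bad
local optima at the true $K$ inflate its standard deviation and can
push the selection off by one.

`dapc_fit()` computes Fisher discriminant axes of the retained PCs
(generalized eigenvectors of between- versus within-class scatter;
singular within-class scatter is ridge-regularized with a logged
epsilon), scales axes to unit pooled within-class variance, and assigns
posterior membership from Gaussian class densities with a shared
within-class covariance and equal priors on the discriminant axes. The
posterior model is a declared choice — discriminant analysis itself
does not define one.

## 4. Frequency-shift inference

Three complementary inferences ask whether cluster frequencies on mixed
reefs changed between censuses. Reefs whose census-1 sample contains a
single cluster are excluded throughout.

**Exact per-reef tests.** `fisher_shift()` tests independence of census
and membership in the focal cluster on the $2\times2$ table of focal
versus pooled-remainder counts, with the probability-mass two-sided
rule (sum of hypergeometric outcomes no more probable than the observed
table) — the same convention as `stats::fisher.test`. P-values across
all reef × cluster tests are Benjamini–Hochberg adjusted.
`permutation_reef_count()` then asks whether the *number* of reefs with
significant shifts for a cluster exceeds chance, by reassigning census
labels within each reef (preserving per-census totals), recomputing
every exact test and the BH adjustment, and using
$p = (\#\{\mathrm{perm} \ge \mathrm{obs}\} + 1)/(B + 1)$. All margins
of each table are fixed under this permutation, so each reef's null
p-value is a precomputed function of one hypergeometric count, which
makes the 1000-iteration null cheap.

A structural caveat the package surfaces honestly: with census samples
of 32 and 8–32 and a focal frequency near 0.25, a single reef's exact
test cannot reach $p < 0.05$ even for complete loss of the focal
cluster (the attainable minimum is about 0.08). The count of
significant reefs is then degenerate at zero regardless of adjustment,
and its permutation p is 1 by convention — valid but powerless. The
count statistic is informative only when per-reef samples are large or
shifts extreme; at this design's sizes the pooled contrast below is the
workhorse.

**Beta-binomial regression.** `betabinom_glm()` fits
$k \sim \mathrm{BetaBin}(n, \pi, \rho)$ with
$\mathrm{logit}(\pi) = X\beta$, shape parameters
$a = \pi(1-\rho)/\rho$, $b = (1-\pi)(1-\rho)/\rho$, so $\rho \in (0,1)$
is the intra-class overdispersion correlation and $\rho \to 0$ recovers
the binomial. The default design is cluster × census + block. The model
is deliberately fixed-effects: rather than a random reef intercept
(which would require Laplace-approximated mixed-model machinery), reef
non-independence is handled by permutation inference that permutes
census labels only within reefs — the exchangeability the design
actually has. Maximization is BFGS from a binomial-GLM warm start;
standard errors come from the observed information. The fit agrees with
an independent fixed-effects beta-binomial implementation to machine
precision on shared fixtures (this is checked in the test suite).
`year_contrasts()` reports each cluster's census-2 − census-1 contrast
on the logit scale with delta-method standard errors and Bonferroni
adjustment across clusters; `year_contrast_permtest()` gives the
corresponding permutation p-value using the pooled logit-frequency
difference (0.5 continuity correction) as the statistic.

**Compositional analysis.** `clr_transform()` replaces zeros by a
pseudocount (default $0.5/\mathrm{total}$, multiplicative replacement),
renormalizes, and takes $\ln(x_i/g(x))$ so rows sum to zero.
`permanova()` computes sequential pseudo-$F$ statistics from partitioned
sums of squared Euclidean distances on the CLR rows (the Aitchison
geometry) and permutes rows, with
$p = (\#\{F_\mathrm{perm} \ge F_\mathrm{obs}\} + 1)/(B+1)$; comparisons
use a relative tolerance of $\sqrt{\varepsilon}$ so permutations that
reproduce the observed partition (numerically tied $F$) count as at
least as extreme — without this, Monte-Carlo p-values are biased
downward whenever few distinct group splits exist.
`dispersion_test()` and `simper()` complete the compositional toolkit:
a permutation test on distances to group centroids (to distinguish
location from dispersion effects) and the per-variable decomposition of
mean Bray–Curtis dissimilarity with permutation p-values.

## 5. Diversity and relatedness

Per-locus gene diversity is $2p(1-p)$, optionally corrected by
$2n/(2n-1)$; `fis()` uses the corrected form and the aggregate ratio
$F_{IS} = 1 - \overline{H_o}/\overline{H_s}$ over polymorphic loci, with
a percentile confidence interval from resampling loci with replacement
(1000 replicates by default). The uncorrected ratio would carry an
$O(1/2n)$ positive bias that distorts CI coverage at small group sizes.

`allelic_richness()` rarefies to $g$ gene copies:
$A_r = \sum_i \big[1 - \binom{N - N_i}{g}\big/\binom{N}{g}\big]$, with
$g$ defaulting to the smallest copy count across the groups being
compared. `wc_fst()` implements the Weir–Cockerham (1984) variance
components $a$, $b$, $c$ per locus and the ratio-of-sums multilocus
estimator $\theta = \sum a / \sum(a+b+c)$; loci monomorphic across the
compared populations are excluded from the sums. The implementation is
validated against a second, loop-based implementation written directly
from the published component formulas, to $10^{-12}$.

**Relatedness.** `wang_relatedness()` is the Wang moment estimator
built on identity-by-state category frequencies. At a biallelic locus
the four published genotype-similarity categories reduce to three
observable ones — identical genotypes, homozygote–heterozygote sharing
an allele, opposite homozygotes — so the two-gene ($\phi$) and
four-gene ($\Delta$) identity coefficients solve a $2\times2$ linear
system of moment equations, and $r = \phi/2 + \Delta$. The expected
category probabilities use allele-frequency moments
$a_m = \sum_i p_i^m$ debiased for reference-sample size with
falling-factorial estimators ($\mathbb{E}[n(n-1)\cdots] =
S(S-1)\cdots p^m$), and loci are weighted by $1/(2a_2 - a_3)$.
Reference frequencies default to the group under study (the
within-cluster convention); this makes the mean pairwise estimate
within a sample centre near zero, so related pairs push unrelated pairs
slightly negative — a property of all frequency-referenced relatedness
estimators, not an error. Validation is by pedigree expectation:
simulated full sibs average $r \approx 0.5$, self-comparisons
$\approx 1$, unrelated pairs $\approx 0$ at 2000 loci.
`bootstrap_mean_relatedness()` resamples individuals with replacement,
extracts pairwise values among distinct resampled individuals
(duplicate-draw self-pairs excluded; empty iterations counted and
skipped), and reports the mean of bootstrap means with a percentile CI;
single-pair groups carry their value flagged as unbootstrapped.

`diversity_trajectory()` regresses each metric on cluster, census,
their interaction and block with a beta likelihood (logit link,
log-precision), after the strictly monotone squeeze
$x' = (x - \min + \varepsilon)/(\mathrm{range} + 2\varepsilon)$,
$\varepsilon = 0.5/n$, for metrics outside $(0,1)$. Term significance is
by likelihood-ratio statistics against permutation nulls that respect
the grouping: metric values permuted within reefs for cluster, census
and interaction terms; the reef-to-block map permuted wholesale for the
block term.

## 6. Trait analyses

`esd_outliers()` is the generalized extreme studentized deviate
(Rosner) procedure with the usual $t$-based critical values; it
requires 15 observations by default and guards zero-variance input.
`cluster_trait_test()` fits the cluster × census + block model by least
squares (Gaussian), logit-binomial (parasite presence) or logit-beta
(proportions), with the same restricted permutation scheme as above and
Tukey–Kramer pairwise contrasts (studentized-range quantiles with the
unequal-$n$ standard error) when the cluster term is significant; with
two groups this reduces exactly to the pooled two-sample t-test.

`correlation_prune()` iteratively removes one member of every
significantly correlated pair with $|\rho| > 0.7$ (Spearman by default,
since rank correlation is what a trait screen on mixed-scale variables
wants; Pearson available): the member with the larger mean absolute
correlation to all other traits is dropped, ties to the later column.

`shift_regression()` is ordinary least squares of the change in
reef-level cluster frequency on z-standardized cluster-by-reef trait
means. Influence is screened with dfbetas; the exclusion rule
"beyond one standard error of the dfbetas" is ambiguous in field usage,
so the default replica mode excludes observations with $|$dfbetas$|$
beyond one standard deviation of that coefficient's dfbetas
distribution, and the conventional $2/\sqrt{n}$ cutoff is available as
an alternative. Both the original and post-exclusion fits are reported.
Added-variable (partial regression) data are returned per trait; by the
Frisch–Waugh identity the added-variable slope equals the
multiple-regression coefficient exactly, which the tests assert.

## 7. Verification strategy and problem sizes

The field data behind the motivating study flow from raw sequencing
reads through an external variant-calling pipeline and are not
reproducible at package scale, so verification is property-based: every
estimator is checked against an independent oracle (brute-force second
implementations, exhaustive enumeration, closed-form identities) and
every inference against simulations with known truth. The problem sizes
are the package's chosen verification conditions: Weir–Cockerham
equivalence on 50 random small fixtures; divergence recovery at
$F = 0.08$, 2000 loci, 100 diploids per population, 20 seeds; exact-test
equivalence for all $2\times2$ tables with $N \le 30$; permutation
calibration over 200 equal-survival datasets; power and sign recovery
over 50 differential-survival seeds; $K$ selection and adjusted Rand
index over 20 seeds at 2600 loci; FIS coverage over 150
Hardy–Weinberg simulations; relatedness over ~50–100 pairs at 1500–2000
loci; condition-driven mortality recovery over 100 cohorts. The
condition-driven scenario couples survival to condition index strongly
enough that the standardized regression effect has $|t| \approx 3$,
matching the signal-to-noise of the field-reported estimate, with the
other size traits left cluster-neutral so they are genuinely null.

## 8. Limitations

- The generator emulates design structure (blocks, mixed reefs,
  families, batches, destructive sampling), not oyster biology: no
  recruitment, larval dispersal, linkage or locus-level selection —
  mortality acts on cluster membership or on a trait, never on
  individual loci. Passing tests therefore demonstrate that the
  *machinery* is correct and calibrated under the design's
  exchangeability structure, not that any particular field dataset
  satisfies those assumptions.
- The count-of-significant-reefs permutation statistic is valid but
  degenerate at this design's census sizes (see §4); its inclusion is
  faithful to the analysis it mirrors, and the pooled permutation
  contrast is the recommended inference at these sample sizes.
- The beta-binomial and beta regressions are fixed-effects with
  restricted permutation inference; they do not estimate among-reef
  variance components.
- Wang relatedness is implemented in its biallelic reduction only,
  matching the biallelic-filtered input; multi-allelic loci are out of
  scope.
- The Evanno-style ΔK adaptation to BIC inherits that statistic's
  inability to evaluate the terminal $K$ values and its sensitivity to
  replicate noise; the sd floor documented in §3 is the package's
  declared resolution of the degenerate case.
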