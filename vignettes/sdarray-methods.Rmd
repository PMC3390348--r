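---
title: "Methods: differential expression, template matching and cross-study statistics in sdarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, template matching and cross-study statistics in sdarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The analysis model

`sdarray` analyzes a three-group expression design — home-cage controls
(HC) and animals sleep-deprived for 24 h (24SD) or 72 h (72SD) — profiled
on single-channel arrays across two hybridization cohorts. The pipeline's
statistical model is deliberately simple and transparent: per-gene
one-way ANOVA for detection, correlation-based template matching for
temporal shape, and exact binomial tail tests for every count comparison.
Each stage is a pure function of an `expression_study` container (signal
matrix, presence calls, missingness mask, sample and gene metadata), and
every stochastic step takes an explicit seed.

## Filtering

Probe sets are kept when they carry annotation grade "A", map to exactly
one gene symbol, and are called present on at least `min_present = 6`
chips. The presence threshold reflects a detection-by-chance argument:
with typical per-chip detection rates, six or more present calls on a
50–70 chip study is unlikely (< 5%) for a noise-level probe set. When
several probe sets map to one symbol the package keeps a single
representative — the one with the most presence calls, ties broken by
higher mean signal, then lexical probe id. This collapsing rule is a
design choice (any deterministic rule works; redundancy is the point),
and the `filter_report` records the count surviving each stage.

## Outlier masking and cohort standardization

Values beyond `k_sd = 2` sample standard deviations of their
treatment-group mean are masked (treated as missing). The rule is applied
in one pass — mean and SD are computed over the group *including* the
candidate value — and never iterated; iterating a trimming rule changes
its breakdown behaviour and is a different estimator. SD throughout the
package is the sample SD (n−1 denominator).

Cohorts hybridized months apart show global background shifts. Per gene
and per cohort, unmasked values are centered and scaled to z-units, then
the cohorts are concatenated. This removes any per-gene additive cohort
constant *exactly* (to floating tolerance) while keeping each cohort's
variability; it does not remove multiplicative or intensity-dependent
batch structure (see Limitations). Masking precedes standardization,
which precedes ANOVA; the order is a design decision — masking on raw
data keeps the outlier rule interpretable in signal units.

Genes with zero within-cohort variance cannot be scaled; their cells in
that cohort are masked and the gene is flagged. Genes left with fewer
than two unmasked values in any group carry no statistics and are
excluded from the multiplicity family.

## ANOVA, FDR and effect sizes

The per-gene test is the classic unbalanced one-way ANOVA,
`F = MS_between / MS_within` on `(k−1, N−k)` degrees of freedom,
vectorized across genes (group sums and sums of squares by matrix
operations, so a 2167 × 53 study tests in milliseconds). The significance
gate is raw `p ≤ 0.05`; the Benjamini–Hochberg q-value is *reported*, not
used as the gate. The headline "median FDR" is the median BH q-value
among the significant genes. An alternative reading — the estimated
false-positive fraction `α·m / n_significant` — is easily computed from
the same table; the median-q reading is the one this package reports
because it is self-consistent with gating on raw p.

Effect sizes are standardized mean differences,
`(x̄_b − x̄_a) / s_pooled`, with the two-group pooled SD. The estimator
carries the usual small upward small-sample bias (a few percent at
n ≈ 16); the package reports the plain estimator rather than a
bias-corrected variant, matching field practice for array effect sizes.

## Template matching

The four temporal templates are encoded as profiles over
(HC, 24SD, 72SD):

| template  | profile    | shape                         |
|-----------|-----------|--------------------------------|
| sustained | (0, 1, 1)  | shifts at 24 h and stays       |
| transient | (0, 1, 0)  | shifts at 24 h, recovers       |
| delayed   | (0, 0, 1)  | shifts only at 72 h            |
| linear    | (0, 0.5, 1)| monotone drift                 |

Only the shapes matter: assignment correlates the gene's three group
means with each profile, and Pearson correlation is invariant to affine
transforms of either vector, so any rescaling of these encodings is
equivalent. A gene goes to the template with maximum |r|; the sign of r
gives the direction (positive = increased with deprivation). Ties in |r|
(measure-zero for continuous data) break by the fixed template order
above. Correlating the three *group means* — rather than all per-chip
values — is the primary mode; per-chip correlation weights groups by
their n and changes the null geometry, and can be built from the same
pieces if wanted.

With three points per correlation, |r| is a coarse statistic; that is by
design — the templates are a classification device, not a model fit. The
Monte Carlo null (below) is what makes the resulting counts
interpretable.

## The Monte Carlo template null

Each iteration replaces the study with an equally-sized matrix of iid
standard normal values, reruns ANOVA, assigns the `p ≤ α` genes to
templates, and tallies counts per (template, direction). Standard normal
is without loss of generality: ANOVA p-values and the correlation
geometry are location/scale invariant, so any iid continuous null gives
the same distribution. Counts are tallied *per direction*: the four
templates capture chance genes unevenly (the transient profile is the
most "isolated" of the four and captures the most), and with
2167 genes, 53 chips (17/16/20) and α = 0.05 the per-direction means are
roughly 14 (sustained), 19 (transient), 13 (delayed), 8.6 (linear),
summing over all 8 cells to ≈ α × 2167 ≈ 108 — the significance count is
assignment-independent, which the test suite asserts. Observed counts
are tested against a cell's null mean with an exact upper-tail binomial,
`P(X ≥ obs)`, `X ~ Bin(n_genes, null_mean/n_genes)`.

## Overlap statistics

For two significant-gene lists A and B on a common background of N
testable genes, the chance overlap is `N·(|A|/N)·(|B|/N)` and the
reported p-value is the exact binomial upper tail at the observed
overlap. Two caveats are deliberate documentation rather than options to
tune:

* **Exact vs normal.** A one-sided normal approximation (with continuity
  correction) is available as `method = "normal"`. At extreme tails the
  two diverge severalfold — e.g. for (N = 2167, |A| = 679, |B| = 405,
  overlap 189) the exact tail is 6.1 × 10⁻⁸ while normal-approximation
  variants give 0.7–2 × 10⁻⁸. Published overlap p-values in this
  literature often come from spreadsheet normal approximations; when
  reconciling against a printed value, variant sensitivity of this size
  must be expected. The exact tail is this package's reference.
* **Binomial vs permutation.** Drawing two fixed-size lists at random
  from the background gives a *hypergeometric* overlap distribution; the
  binomial test treats per-gene significance as independent. On small
  backgrounds (N ≤ 50) the deterministic gap between the two tails is of
  order 0.02–0.08 — far larger than Monte Carlo error of a large
  permutation sample. The tests assert the permutation oracle against
  the hypergeometric exactly and the binomial against the oracle within
  the analytic model gap.

The m-study same-direction expectation is
`N · Π(|Lᵢ|/N) · 2^(1−m)` under independent equiprobable signs; for
studies that published only curated gene lists, replication is tested
with a fixed-baseline binomial (`list_comparison_test`), the baseline
being the present study's significant fraction halved for directional
agreement.

## Power equalization

To ask whether a 53-chip study finds more genes than a 21-chip study
because of biology or just power, `subsample_significance_counts` redraws
21-array subsets (simple random without replacement, rejecting draws that
leave any group below 2 arrays; group-proportional stratified sampling is
available by flag), re-tests, and histograms the significant-gene counts.
`fit_gaussian_to_histogram` fits `A·exp(−(x−μ)²/2σ²)` to the (bin center,
frequency) pairs by Levenberg–Marquardt least squares (initialized at the
sample mean, SD and modal frequency; default bin width 10 counts), and
`power_equalized_p` reports the fitted-curve area below the comparison
count, `Φ((c−μ)/σ)`. The p-value comes from the fitted curve, not the
empirical ECDF — the fit is the declared summary of the histogram — but
the raw counts are returned so the empirical quantile is one line away.

## EASE overrepresentation

`ease_score` is the conservative DAVID variant of the one-tailed Fisher
exact test: the overlap cell is decremented by one before taking the
hypergeometric upper tail, so single-gene overlaps can never score below
1 and every EASE p dominates the classical Fisher p (asserted
exhaustively for N ≤ 30 in the tests). Categories are retained when the
*significant-gene* overlap lies in [3, 50]; no multiple-testing
correction is applied to enrichment p-values (a BH column is emitted for
convenience).

# The synthetic-study generator

`generate_study` emulates the target design so that every stage has a
ground truth to be tested against:

* group sizes 17/16/20 (HC/24SD/72SD), 53 chips, 2167 genes by default;
* two cohorts, each containing every group, with a cohort-1 share of
  37/69 (the cohort share of profiled animals in the emulated design) and
  an additive cohort-2 background shift of −0.5 log-signal units —
  direction and rough size chosen to mimic a visible global background
  decrease that standardization must remove;
* planted genes following the four templates (default 5% of genes per
  template, 50/50 up/down) with mean shifts of `effect_size × noise_sd ×
  template value`; effect size defaults to 2 within-group SD, a strong
  but realistic array effect that yields high but not saturated ANOVA
  power at n ≈ 17;
* iid Bernoulli presence calls at rate 0.9 — filtered, well-expressed
  genes are present on most chips.

What the generator does *not* emulate: probe-level structure,
intensity-dependent variance, correlated genes (co-regulation), or
multiplicative batch effects. Passing tests therefore demonstrate that
the statistical machinery is correct and calibrated under the stated
model, not that the model captures every property of real array data —
in particular, between-gene correlation inflates the variance of
genome-wide counts on real data relative to the iid null.

# Numerical choices and degenerate inputs

* Sample SD (n−1) everywhere; single-pass outlier rule; stage order
  mask → standardize → ANOVA.
* Zero-variance genes: flagged, excluded from statistics and from the BH
  family. Equal group means with nonzero within-variance give F = 0,
  p = 1. Zero within-variance with distinct means gives p = 0.
* `bh_fdr` errors on p outside [0, 1]; q is returned in input order.
* `assign_templates` returns constant-mean genes unassigned rather than
  erroring; downstream tallies skip them.
* Gaussian fitting requires ≥ 5 non-empty bins and errors on a
  degenerate (constant) histogram; σ is reported as |σ| since the
  Gaussian is even in it.
* Subsample draws that violate the ≥ 2-per-group constraint are rejected
  and redrawn, which slightly biases the sampling toward balanced
  subsets; the stratified mode makes that balance explicit instead.
* All exact tail tests use `pbinom`/`phyper` upper tails directly; no
  normal approximations are used unless explicitly requested.

# Problem sizes in the test suite

The suite exercises the full 2167 × 53 design where the claim depends on
it (Monte Carlo template null at 1000 iterations, template recovery with
200 planted genes per template) and smaller designs (a few hundred genes,
6–16 chips per group) for structural and oracle checks; these sizes give
Monte Carlo standard errors comfortably inside the asserted windows while
keeping the suite fast. Null calibration uses 2000–5000 genes, where the
3-SD binomial window on the significant fraction is ±1.5 percentage
points.

# Known limitations

* The pipeline assumes approximately normal within-group noise; the
  outlier mask truncates heavy tails but the F-test's null calibration
  under strong non-normality is not asserted.
* Between-gene independence is assumed by the binomial count tests and
  the Monte Carlo null; real co-expression makes genome-wide count
  variances larger than binomial.
* The EASE stage tests user-supplied gene sets one at a time; no
  category clustering or ontology handling is included.
* Per-cohort standardization removes additive cohort effects only.
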