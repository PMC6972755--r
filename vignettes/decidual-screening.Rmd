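---
title: "Methods: day-normalized decidual screening and its supporting single-cell computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-normalized decidual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deciduoscreen)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical conventions chosen
where several were defensible.

## 1. Day-normalized percentile scoring

### Model

qPCR marker expression is recorded as ΔCt = Ct(target) − Ct(L19); lower
ΔCt means higher expression. Because decidual genes change systematically
across the luteal phase, a raw ΔCt from an LH+7 biopsy is not comparable
with one from LH+10. The reference-curve machinery therefore builds, per
gene and per cycle day (LH+6..LH+11), an empirical quantile function on
the *expression score* `s = −ΔCt`, and maps any new sample to
`100 × F̂_day(s)`.

Percentiles are always percentiles of expression. This orientation is
forced by the downstream rules: "SCARA5 at or below the 30th percentile"
must mean *low SCARA5 expression*, i.e. *high* SCARA5 ΔCt. uNK-cell
abundance (CD56⁺ cells per 100 stromal cells, averaged over three scored
images) is day-normalized with the same machinery, oriented so more uNK
cells give a higher percentile.

### Numerical conventions

* **Plotting positions.** The empirical CDF uses midrank (Hazen)
  positions `(rank − 0.5)/n`, with tied values collapsed to their average
  rank, and linear interpolation between distinct reference values. This
  makes a reference sample's self-percentile exactly `100(i − 0.5)/n`, so
  self-assignment is uniform by construction — the calibration property
  the test suite checks with Kolmogorov–Smirnov tests.
* **Clamping.** Queries below/above the reference range return 0/100. A
  query equal to the reference minimum or maximum evaluates at its own
  plotting position, not at the clamp.
* **Sparse days.** Days with fewer than `min_per_day` (default 20)
  reference samples are pooled with the nearest neighbouring day, ties
  resolved towards the earlier day, and the pooling is recorded in the
  curve metadata. A realistic reference (30–46 samples per day) never
  pools; the rule is a guard for thin user-supplied references.
* **Serialization.** Curve sets serialize to JSON at full floating-point
  precision; written-then-read curves reproduce percentiles to 1e-9.

## 2. Defect rules, bins, and cohort statistics

The rule set (`defect_rules`, defaults low = 30, high = 70) classifies a
subject's percentile triple:

* decidualization failure: SCARA5 ≤ low and DIO2 ≤ low;
* excessive decidual senescence: SCARA5 ≤ low and DIO2 ≥ high;
* uNK-cell deficiency: uNK ≤ low with both markers strictly inside
  (low, high);
* otherwise none.

Boundaries are implemented literally (inclusive ≤/≥ for the marker rules,
strict interior for the uNK rule's marker window). The three regions are
disjoint — the first two require SCARA5 ≤ low, the third SCARA5 > low, and
the first two differ in a DIO2 condition that cannot hold simultaneously —
so every triple receives exactly one label; the test suite verifies this
exhaustively on the 101³ integer percentile grid. Triples matching no rule
are "none" even when individually extreme (e.g. low SCARA5 with mid-range
DIO2): the aberrant set is defined as the union of the three named
defects, nothing more.

**Bins.** Cohorts are additionally binned by SCARA5 percentile + uNK
percentile (DIO2 participates in classification but not in the sum). The
bin boundaries of a four-bin analysis on this sum are not derivable from
published bin occupancies, so the package defaults to equal-width bins on
[0, 200] with edges {50, 100, 150}, half-open `[lo, hi)` with the top bin
closed, and exposes the edges as configuration. This is an interpretation,
and analyses that depend on bin membership should report the edges used.

**Tests.** `cohort_contingency` uses Fisher's exact test (two-sided, by
exact hypergeometric enumeration) with the conditional odds-ratio estimate
for 2×2 tables, and the chi-squared test *without* continuity correction
for larger tables. `screen_cohort` reports: aberrant-by-group (Fisher),
each defect versus the rest by group (chi-squared, the convention for
per-defect comparisons), and lowest-versus-highest bin by group (Fisher).
Whether a published extreme-bin contrast used the 2×2 extreme table or the
full 4×2 table is ambiguous; the package computes the extreme-bin 2×2
test and also returns the full bin table so either can be reported.

## 3. Single-cell computations

### Knee-point cell calling

Barcodes are ranked by descending reads; the cumulative read fraction is
plotted against rank (both axes normalized to [0, 1]); the knee is the
point of maximum perpendicular distance to the chord joining the curve's
endpoints. Barcodes at or beyond the knee are ambient-RNA candidates and
are excluded. This chord construction is deterministic and avoids
derivative estimation on a noisy curve.

*No-knee flag.* A curve is declared knee-free when the maximum distance is
below 0.25 × chord length. The threshold is a knee-*prominence* criterion,
not a numerical-zero guard: measured prominence is ~0.05–0.15 for smooth
single-population read distributions (which have curvature everywhere but
no corner) and ≥ 0.4 for genuine cell/ambient mixtures. A much smaller
tolerance would label a shoulder of any unimodal distribution as a knee;
0.25 cleanly separates the two regimes while still flagging the flat and
single-population cases as knee-free.

### QC filtering

Thresholds default to the standard droplet values: cells with < 200 or
> 4500 detected genes removed (empty/low-quality and doublet guards),
cells with > 5% mitochondrial transcripts removed (damaged cells), genes
detected in < 3 surviving cells removed. The order is fixed — cell rules
first, gene support computed on surviving cells — because the result is
order-dependent and reproducibility requires pinning it. The operation is
idempotent. Mitochondrial genes are recognized by identifier prefix
(default `MT-`), keeping the filter annotation-free.

### Normalization and imputation

Raw counts are scaled per cell to the *median* library size and
log1p-transformed. The choice (rather than a fixed 10⁴ scale factor) keeps
the output on the scale of the data at hand; it is configurable in effect
because proportional profiles map to identical output either way.

Imputation is a plain graph-diffusion smoother: a symmetrized binary
k-nearest-neighbour affinity over cells (self-loops included) is
row-normalized into a Markov transition matrix `M`, and expression is
replaced by `X Mᵗ` (defaults k = 15, t = 3). `t = 0` is the identity;
constant genes are eigenvectors and pass through unchanged; on regular
graphs `M` is doubly stochastic and per-gene means are preserved. This is
deliberately the *minimal* member of the Markov-affinity imputation
family: it preserves the property the downstream step needs (smoothing
before thresholding) while admitting an exact matrix-power oracle in the
tests. It lacks the adaptive kernels and spectral rescaling of full
implementations, and imputed values should be treated as denoised
visualization/partitioning inputs, not as expression estimates.

### Marker-pair partitioning and marker tests

`partition_by_marker_pair` thresholds each marker at the midpoint of its
observed range on the imputed matrix (the most literal reading of "the
midpoint of the expression levels"; range midpoint, median and mean
coincide only for symmetric distributions, and the choice is flagged
here). Cells above the first marker's midpoint and below the second's form
one enriched class, the mirror image forms the other, and everything else
is intermediate; the classes partition the cells. A zero-range marker is
an error, since its midpoint is undefined.

`wilcoxon_markers` runs a two-sided Wilcoxon rank-sum test per gene with
Bonferroni adjustment over the tested genes — deliberately conservative,
matching common marker-test practice in droplet toolkits.

## 4. Co-expression modules and the congruency statistic

### Correlation k-means and the figure of merit

Genes are clustered on `1 − r(profile, centroid)` (Pearson). Internally
profiles are centered and unit-normalized, making the algorithm spherical
k-means, whose assignment and update steps both monotonically decrease the
objective (the tests assert the trace is non-increasing). Initialization
is k-means++-style on correlation distance; Lloyd iterations are capped at
50; the best of `n_restarts` (default 10) by within-cluster distance sum
is kept, deterministically given a seed. Constant-profile genes have
undefined correlation and are reported in a separate "flat" module rather
than silently dropped.

The number of modules is chosen by a figure of merit: leave out one
condition, cluster on the rest, and score the root-mean-square deviation
of the left-out condition's values from their cluster means; sum over
left-out conditions and divide by `sqrt((n − k)/n)` to remove the trivial
decrease with k. The suggested k is the elbow — the largest second
difference of the adjusted curve. On seven planted near-orthogonal
temporal patterns (noise sd 0.25 against unit-variance patterns) the
elbow lands on k = 7 in ≥ 80% of seeded runs; patterns that are mutually
correlated merge earlier, which is a property of the data, not a failure
of the scan.

### Gene-pair congruency

For each unordered pair of branch genes, the Pearson correlation across
cells is computed in each of two datasets (e.g. an in vitro time course
and in vivo biopsies, both after imputation) and summed. The sum lies in
[−2, 2]; |sum| > 1 declares the pair congruent — co-regulated in the same
direction in both datasets. Self-pairs are reported with sum exactly 2 and
excluded from enrichment; pairs involving a zero-variance gene are flagged
undefined and excluded but counted.

Enrichment against chance uses a label-permutation null by default: the
gene labels of the second dataset are shuffled, the congruent fraction is
recomputed, and `p = (1 + #{null ≥ obs})/(1 + n_perm)`. This needs no
distributional assumptions and conditions on both correlation structures.
A hypergeometric variant is provided for the two-evaluation design —
pairs congruent in two separate comparisons (e.g. against two biopsy
days) form two subsets of the pair universe, and their overlap is tested
against Hypergeometric(N, K, k) — because that is the only urn this
statistic pins down unambiguously; other hypergeometric parameterizations
would require an arbitrary choice of "draws". When a single two-dataset
comparison is tested, use the permutation null.

Branch-gene *ranking* is taken as input: trajectory/branch modelling is
out of the package's scope, and `rank_branch_genes` (absolute
between-state mean difference) is a convenience for synthetic data only.

### Marker-candidate filter

`select_candidate_markers` applies three sequential filters to branch
genes: (1) stromal enrichment — rank-sum significant versus *every* other
cell type with log2 fold-change ≥ 1 (pseudocount 1) at adjusted p ≤ 0.05;
(2) epithelial non-regulation — max/min temporal fold-change in glandular
epithelium ≤ 1.5; (3) stromal temporal regulation — by default the same
fold-change bound must be *exceeded* in the stromal time course
("changing"), with "increasing"/"decreasing"/"any" variants. The
published criteria are qualitative; all three thresholds are exposed in
`marker_criteria`, and the audit table records which filter removed each
gene so threshold sensitivity is inspectable. Filter 1 is the conjunction
"significant and fold-change above threshold"; it intentionally has no
separate direction clause, so that slackening every threshold passes
every gene.

## 5. The synthetic-data generators

The generators define the conditions under which the pipeline is tested;
they are first-class, tested code.

**Cohorts.** Each subject draws a latent class — normal, decidualization
failure, excessive senescence, uNK deficiency — from per-group
prevalences. Defaults plant an aberrant incidence of 14% in controls
(5/4/5%) and 44% in RPL (8/16/20%), the contrast a screening study of
this design should detect at 90/89 subjects. The class is realized in
percentile space (failure: both marker percentiles uniform on [0, 30];
senescence: SCARA5 on [0, 30], DIO2 on [70, 100]; uNK deficiency: markers
uniform on (30, 70), uNK on [0, 30]; normal: rejection-sampled from the
complement of all three regions, so zero-prevalence cohorts are
aberrant-free *exactly*). Percentiles are then inverted through the
generative quantile functions to observables.

The generative ΔCt model is Normal per gene per day — the simplest model
supporting exact quantile inversion. No distributional form for
between-subject ΔCt is established empirically, so this is a stand-in:
day-varying means (SCARA5 ΔCt falling 9.5→6.0 across LH+6..11, DIO2
8.0→6.0, sd 1.5) emulate rising decidual expression across the window,
and the day trend is what makes day-normalization non-trivial. uNK
percentages are Normal(8, 2.5) and are emitted as three integer
(CD56⁺, stromal) image pairs with 150–350 stromal cells per image, so the
quantification step is exercised; integer rounding perturbs the realized
percentage by < 0.35.

**Count matrices.** Cells occupy DC / snDC / trunk states with default
proportions 0.78/0.13/0.09 (the day-6 composition of a decidualizing
culture). Module genes are 8-fold elevated in their own state; counts are
negative binomial (dispersion 0.3) scaled to a mean library of 2000,
followed by independent Bernoulli dropout (rate 0.2). This emulates the
features the preprocessing stages consume — planted modules, overdispersed
counts, zeros — and *not* transcriptome-wide realism: no batch effects, no
doublets, no gene-length or capture biases, no continuous pseudotime.
Passing recovery tests on these data shows the operations are correct
under their stated models, not that they are robust to everything real
data does.

**Barcode reads.** Real barcodes draw log-normal reads (sdlog 0.25)
around their mean, ambient barcodes negative binomial around a much lower
mean (defaults 800 real at 2000 reads, 7200 ambient at 20, matching the
~10:1 barcode excess and ~800-cell yield of a typical droplet run).

## 6. Problem sizes and determinism

All simulation-backed checks run at sizes chosen to make their sampling
noise small relative to the effect under test while keeping the whole
suite interactive: cohort recovery at 500 subjects per arm against
1000-per-day references (curve-estimation noise ≈ 1.5 percentile points,
small against the 30-point class regions); centile calibration at the
realistic 42-per-day (~250-biopsy) reference depth; congruency
calibration at 200 replicates of 199 permutations; FOM recovery at 20
seeded runs of 70 genes × 9 conditions. Every stochastic function takes
an explicit seed and restores the caller's RNG state, so identical
configurations reproduce identical outputs bytewise.

## 7. Known limitations

* Percentile estimates inherit the reference cohort's sampling noise;
  near the 30th/70th rule boundaries this spills borderline subjects
  between classes, attenuating recovered prevalences by roughly 5–10%
  relative at realistic reference depths (visible in the worked example).
  The rules themselves are step functions; no uncertainty is propagated
  into the defect call.
* The ΔCt and uNK generative distributions are Normal stand-ins; real
  references may be skewed, and the percentile machinery (being empirical)
  handles that, but planted-truth recovery rates quoted here would not
  transfer verbatim.
* The four-bin edges are a documented interpretation, not a reproduction
  of any published binning.
* The diffusion imputer and the range-midpoint threshold are simple,
  documented conventions; both have more sophisticated alternatives whose
  behaviour on real data can differ (adaptive-kernel imputation, mixture
  thresholds).
* Trajectory inference, clustering/embedding, deconvolution and gene
  ontology analysis are out of scope; branch-gene lists and cell-type
  summaries enter as inputs.
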