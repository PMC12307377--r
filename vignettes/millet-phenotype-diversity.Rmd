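---
title: "Evaluating phenotypic diversity in germplasm panels with phenodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating phenotypic diversity in germplasm panels with phenodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

## The problem

A germplasm bank holds hundreds to thousands of accessions of a crop —
locally adapted landraces, breeding lines, released cultivars. Before
any of that material can be used in a breeding program, the collection
has to be characterized: how variable is each trait, how much diversity
does the panel carry, which traits move together, and which accessions
combine superior values across many traits at once. `phenodiv`
implements this evaluation for panels scored on a mixed descriptor set:
continuous agronomic measurements and qualitative characters coded as
small integers against standard descriptor lists. The bundled registry
(`millet_traits()`) is the 25-trait foxtail millet set — 11 quantitative
traits (seedling-to-spike period and growth period in days, main spike
and stem length in cm, stem thickness in mm, single-spike weight,
single-spike grain weight and 1000-grain weight in g, and the CIELAB
L*/a*/b* grain-color coordinates) and 14 coded qualitative traits
(pigmentation, spike morphology, leaf posture, tillering, lodging
resistance). Registries are first-class objects, so other crops'
descriptor sets drop in without code changes.

## Variability and diversity statistics

Two families of statistics summarize a panel trait by trait.

**Coefficient of variation.** `descriptive_stats()` reports mean, sample
standard deviation (the n−1 estimator throughout the package), extremes,
range, and CV = 100·S/X̄. Qualitative traits report the CV of their
integer codes (`qualitative_cv()`): dimensionally awkward but standard
in germplasm characterization, and the convention under which published
qualitative CVs are exactly reproducible from published category counts
(we verified, e.g., codes 1–4 with counts 1066/235/22/235 give 66.20%
only with the n−1 denominator — the sanity check that fixed this
choice).

**Shannon–Wiener index.** H′ = −Σ Pᵢ ln Pᵢ (natural log, 0·ln 0 := 0).
For qualitative traits the Pᵢ are the observed category frequencies
(`qualitative_profile()`). Continuous traits are first stratified
(`stratify_ten_classes()`) into 10 classes anchored on the trait's own
mean and SD: class 1 collects x ≤ X̄ − 2S, class 10 collects
x ≥ X̄ + 2S, and the eight interior classes advance in 0.5 S steps.
This makes H′ of a continuous trait a fixed functional of its shape: for
any (large) normal sample the class probabilities are the Φ increments
(0.0228, 0.0441, 0.0919, 0.1499, 0.1915, mirrored), giving
H′ = 2.0878 — the oracle value our property tests check at n = 10⁶.

Numerical conventions the stated scheme leaves open, fixed here:

* Interior classes are half-open [lower, upper), so a value exactly at
  the mean lands in class 6. The two extreme classes are closed, as
  their definitions demand; at X̄ ± 2S exactly, the closure wins.
* A constant trait (S = 0) cannot be stratified; we emit a degenerate
  profile (all mass in class 6, H′ = 0) with a classed warning rather
  than an error, so a panel with one invariant trait still reports.
* H′ is computed over occupied classes only; empty classes contribute
  nothing (the 0·ln 0 convention).

Two consistency notes on the published reference table of qualitative
counts bundled with the package: the leaf-sheath-color and
seedling-leaf-color rows have their CV and H′ printed transposed
relative to what their own counts imply (the formulas give H′ 0.87 /
CV 51.86 for the three-category leaf-sheath counts and 0.44 / 31.71 for
the two-category seedling-leaf counts); and the hull-color H′ implied by
its seven printed class counts is 0.48, not the printed 0.44. The test
suite asserts the recomputed values — the formulas, not the typesetting.

## Correlation and principal components

`trait_correlation()` reports pairwise-complete Pearson r with
two-sided p-values from t = r√((n−2)/(1−r²)). No multiple-testing
correction is applied by default (matching the field's reporting
practice); a `p_adjust = "BH"` flag is available.

`trait_pca()` eigendecomposes the correlation matrix of all 25 traits —
qualitative codes included, which is unusual for PCA but is the
established convention for this evaluation (the published loading tables
carry every qualitative trait). The quantities follow the SPSS-style
presentation used in germplasm studies:

* eigenvalues λ (summing to p = 25, the trace of a correlation matrix);
* loadings = eigenvector·√λ (trait–component correlations);
* score coefficients = unit eigenvector = loading/√λ — we verified this
  identity against the bundled reference tables (e.g. PC1 loading 0.54
  with λ = 3.31 implies coefficient 0.297 vs the printed 0.298; 247 of
  250 cells agree within ±0.005, the residual being 2-dp print
  quantization);
* contribution rate = 100·λ/p percent, cumulated over components.

Retention keeps components with λ > 0.95 up to a cap of 10 (both knobs
exposed). Eigenvector signs are indeterminate; we fix each component so
its largest-|loading| trait is positive, and eigenvalue ties break by
input trait order, making results deterministic. `component_scores()`
computes Fᵢ = Σⱼ cⱼᵢ zⱼ. With unit-eigenvector coefficients each score
column has sample variance λᵢ on the fitting panel (not 1 — the variance
-1 alternative would divide by a further √λ, which the published
coefficient matrices rule out).

## Composite F-value and ranking

`composite_weights()` normalizes the retained components' contribution
rates to weights wᵢ = rateᵢ/Σrate and `composite_f()` forms
F = Σ wᵢFᵢ per accession. Rounding weights to 3 decimals (the published
presentation) is available but off by default; the published rounded
weights sum to 0.999, which we document rather than "fix".
`rank_accessions()` sorts by descending F with dense ranks, ties
sharing the smaller rank and breaking deterministically by accession id.

Two normalizations feed the scores (`score_accessions()`): z-scores
(default) and the membership function u = (x − x_min)/(x_max − x_min).
Both appear in the literature of this evaluation; z-scoring is the only
mode consistent with score-coefficient matrices derived from a
correlation-matrix PCA, hence the default. Since both are increasing
affine maps per trait, rankings under the two modes are strongly
concordant (asserted as Spearman ρ > 0.9 on a fixed synthetic panel).
Accessions with any missing trait are excluded from scoring with a
logged record. Because z-scoring absorbs shifts, adding a constant to a
raw trait provably leaves F unchanged — one of the suite's invariants.

## Clustering

`cluster_accessions()` runs agglomerative clustering on Euclidean
distances over z-scored traits. The linkage is not dictated by the
evaluation itself; we default to Ward (`ward.D2`, merge heights on the
distance scale), the standard choice for trait dendrograms, with
average and complete linkage exposed for sensitivity runs. The tree is
cut at k = 5 by default (the group count used for the reference millet
panel); labels are renumbered by descending cluster size (ties by first
member id) so reports are stable across runs. An `exclude` argument
allows dropping a trait, e.g. to mimic a 24-trait run.
`cluster_profiles()` tabulates per-cluster, per-trait summaries (the
data behind violin plots), and `as_newick()` serializes the dendrogram
with accession-id leaves and telescoping branch lengths (root-to-tip
distance equals the root merge height — the export is ultrametric by
construction, which the tests verify by re-reading it with `ape`).

## The synthetic cohort: what it emulates, and what it does not

No accession-level data are distributed with the evaluation this
package implements, so `generate_cohort()` stands in. Its defaults are
the published marginal summaries of the 1,558-accession millet panel:
`table3_targets()` (quantitative means/SDs/ranges) and
`table4_targets()` (qualitative category frequencies; normalized by
their own row totals, one published row summing to 1,557). Design
choices:

* **Moment-matched truncated normals.** Quantitative traits are drawn
  from a normal truncated to the published [min, max]. Truncation
  shrinks dispersion (for main stem length, bounds at −3.1/+2.7 SD
  would bias the SD ≈ 2% low), so the underlying (μ, σ) are solved by
  fixed-point iteration such that the *truncated* distribution attains
  the target mean and SD exactly. Out-of-range draws are resampled from
  the marginal (up to 1000 rounds, then clipped), so range invariants
  hold for every cell.
* **Optional correlation.** A user-supplied PSD correlation matrix over
  quantitative traits is induced by Cholesky-mixing the per-trait
  standard-normal streams before marginal transformation — a Gaussian
  -copula-style contract. Qualitative traits are sampled independently
  and categorically.
* **Per-trait substreams.** One master seed; each trait draws from a
  deterministically derived substream, so adding or re-targeting one
  trait does not perturb the others, and identical specs give
  byte-identical tables.

The generator emulates *marginals* (plus any injected correlation). It
does not emulate the real panel's correlation network, genotype or
pedigree structure, year-to-year environment effects, or
material-class/trait associations. Consequently, pipeline outputs that
depend on the joint distribution — cumulative contribution of the top
10 components, cluster memberships, individual F-values — are *not*
expected to reproduce published panel-level results, and the tests do
not pretend otherwise: they assert parameter recovery (means, SDs,
category frequencies, injected correlations), formula-level
reproduction of published desk-scale numbers, and structural
invariants. Passing tests certify the machinery, not field biology.

## Fixtures and problem sizes used by the test suite

Sampling-based checks run at sizes where their tolerance bounds are
comfortable: marginal recovery at n = 10⁵ (±0.2 on a mean with SD 20;
±0.5 pp on an 89.7% category), injected correlations at n = 10⁴
(envelopes ±0.05), the normal-entropy oracle at n = 10⁶ (±0.01), the
SVD-vs-eigendecomposition cross-check on 100 random 25-trait panels,
and Ward recovery on a 1,558-row fixture with five planted centroids —
groups offset by ±2 published SDs in the quantitative traits with
within-group SD scaled to 0.4×, and qualitative distributions
concentrated (0.85) on group-specific categories so that every trait
carries the planted structure; recovery is scored by adjusted Rand
index > 0.95 against the generating labels. Brute-force oracles
(linear-scan class assignment, exhaustive greedy Ward agglomeration)
are implemented independently in the test helpers.

## Known limitations

* Qualitative codes enter CV, correlation and PCA as numbers; this is
  the field's convention for this evaluation, not a measurement-theory
  endorsement. Polychoric correlations or FAMD-style mixed-data
  ordination would be defensible alternatives and are out of scope.
* PCA retention (λ > 0.95, ≤ 10) follows the reference evaluation; on
  near-spherical simulated panels the retained components explain far
  less variance than on correlated real data.
* Two-year averaging of qualitative traits is not well defined; we use
  the modal code with earlier-year tie-break, documented and
  deterministic.
* `hclust` is O(n²) in memory; panels beyond ~10⁴ accessions need a
  different clustering backend.
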