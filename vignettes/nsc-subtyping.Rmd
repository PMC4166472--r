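---
title: "Shrunken-centroid subtyping: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrunken-centroid subtyping: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nscsubtype)
```

# Scope

`nscsubtype` assigns tumor samples to molecular subtypes — canonically the
ten integrative-cluster groups `IC1`…`IC10` of breast cancer, defined by
recurrent copy-number alterations that deregulate expression in *cis* — using
a nearest-shrunken-centroid classifier trained on an index (reference)
cohort. The package covers the three-step single-study workflow (feature
matching, z-score normalization, classification with centroid
re-estimation), the per-subtype goodness-of-fit diagnostic, the evaluation
statistics used to compare classifications across studies, and a synthetic
cohort generator that reproduces the statistical structure the classifier
assumes.

# The classification model

## Centroids, dispersions, offsets

Let $x_{ij}$ be the normalized value of feature $j$ in sample $i$, with $K$
classes of sizes $n_k$ ($n$ samples total, $p$ features). The fitted model
(`nsc()`) consists of

* class centroids $\bar x_{kj}$ and the overall centroid $\bar x_j$
  (means over non-missing cells);
* the pooled within-class standard deviation
  $s_j^2 = \frac{1}{n-K}\sum_k \sum_{i \in k} (x_{ij} - \bar x_{kj})^2$,
  guarded by the fudge constant $s_0 = \operatorname{median}_j(s_j)$ that
  keeps low-variance features from dominating;
* standardized offsets
  $d_{kj} = (\bar x_{kj} - \bar x_j) / \bigl(m_k (s_j + s_0)\bigr)$ with
  $m_k = \sqrt{1/n_k - 1/n}$, so that $m_k (s_j+s_0)$ estimates the standard
  error of the class-vs-overall mean difference.

The offsets are soft-thresholded at the shrinkage threshold $\Delta$,
$d'_{kj} = \operatorname{sign}(d_{kj}) \max(|d_{kj}| - \Delta, 0)$, and the
shrunken centroids rebuilt as
$\bar x'_{kj} = \bar x_j + m_k (s_j+s_0)\, d'_{kj}$. Features whose offsets
vanish for every class carry no between-class information; $\Delta$ thus
performs embedded feature selection.

A sample is scored per class by
$$\delta_k(x) = \sum_j \frac{(x_j - \bar x'_{kj})^2}{(s_j + s_0)^2}
  - 2 \log \pi_k,$$
assigned to $\arg\min_k \delta_k$, with posteriors
$e^{-\delta_k/2} / \sum_l e^{-\delta_l/2}$ computed after subtracting the
row minimum so the exponentials cannot underflow collectively.

The model assumes features are independent given the class and share a
per-feature dispersion across classes (diagonal, homoscedastic within
feature) — adequate for z-scored expression panels, wrong for strongly
co-regulated feature blocks, which the shrinkage only partly mitigates.

## Conventions that differ between shrunken-centroid descriptions

* **$m_k$.** Both $\sqrt{1/n_k - 1/n}$ and $\sqrt{1/n_k + 1/n}$ circulate.
  The default is the *minus* form (the variance of
  $\bar x_{kj} - \bar x_j$ when class $k$'s samples are part of the overall
  mean); `m_convention = "plus"` selects the other dialect so
  cross-implementation differences are explicit rather than silent.
* **Priors.** Empirical class frequencies by default (the re-estimation
  target is the reference cohort itself); `prior = "uniform"` is available
  when the deployment population is believed balanced.
* **Tie-breaking.** Exact ties in $\delta$ go to the larger prior, then to
  class-label order — deterministic by construction.
* **Degenerate dispersions.** If every $s_j = 0$ (noiseless fixtures),
  $s_0$ is floored at $10^{-6}$ so all scores stay finite.

## Threshold selection

`nsc_cv()` lays `n_thresholds = 30` equally spaced values on
$[0, \max_{kj}|d_{kj}|]$, assigns stratified folds (`n_folds = 10`, capped
at the smallest class size), refits centroids per training split and counts
held-out misclassifications at each grid value. The chosen $\Delta^\*$ is the
*largest* grid value attaining the minimal total error: among
indistinguishable models, prefer the sparsest. Fold assignment is the only
random element; under a fixed `seed` the folds, the error curve and
$\Delta^\*$ are bit-reproducible, and the RNG state of the calling session is
restored afterwards. Inside CV, fold fits tolerate singleton classes (a rare
class can lose all but one training sample to the held-out fold); user-level
fits require at least two samples per class.

## Missing features and missing cells

The two mechanisms are deliberately distinct:

* **A study lacks features** (e.g. provides 579 of 612 catalog genes). The
  model is *re-estimated* against the reference cohort on the available
  subset (`retrain_on_features()`, used by `subtype_cohort()`): fresh
  centroids, fresh cross-validated threshold. Below
  `min_feature_fraction = 0.5` of the reference panel the fit refuses and
  suggests copy-number or combined mode.
* **Individual cells are missing.** At load they are flagged, never imputed.
  At fit, features missing in more than half the samples are dropped with a
  warning; otherwise missing cells are simply excluded from means and sums
  of squares. At prediction, a sample's $\delta$ sums run over its present
  features and are rescaled by $p_{\text{model}} / p_{\text{present}}$ so
  scores stay comparable across samples with different missingness.

# Feature matching and normalization

**Matching** (`match_expression_features()`) is exact and case-sensitive, by
probe id or by gene symbol; in gene mode, several dataset rows mapping to one
catalog gene are aggregated by their per-sample arithmetic mean (symmetric,
and the natural summary absent probe-quality weights). No alias expansion is
attempted — alias tables are annotation-version-dependent and would make
matching irreproducible. Segmented copy-number calls are summarized to gene
level (`segments_to_gene_matrix()`) as the overlap-length-weighted mean of
the log ratios of all segments intersecting the gene span; a
`rule = "midpoint"` dialect (value of the segment covering the gene
midpoint) is provided because the position-matching convention is not
standardized across tools. Coordinates are 1-based fully closed throughout.

**Normalization** (`zscore_features()`) scales each feature to mean 0, sd 1
(denominator $n-1$) within the dataset at hand — reference and new study
alike — so any cohort lands on the reference scale. This within-dataset
z-scoring is what makes classification invariant to per-feature positive
affine distortions, the dominant platform effect; it is *not* a
quantile-level alignment and will not fix rank-distorting platform effects.
Zero-variance features (sd $< 10^{-12}$) are dropped and recorded. A
single-sample matrix is rejected rather than silently producing
undefined sds.

# Goodness of fit

For each subtype with at least one assigned sample, `per_class_gof()`
correlates (Pearson) the study's subtype-average profile with the training
centroid over the shared features. The correlation target is the *unshrunk*
centroid — the reference class mean — since the diagnostic asks how well the
study reproduces the reference profiles, not the sparsified discriminant.
The study-level statistic is the unweighted mean over non-empty subtypes:
weighting by class size would let one abundant subtype mask poor fit in rare
ones, which is exactly what the diagnostic must expose. Empty or
zero-variance classes are reported as absent with a reason rather than
contributing a defined-by-fiat value.

# Evaluation statistics

* `agreement()` cross-tabulates two labelings over the sorted union of their
  label spaces and reports observed agreement, chance-expected agreement
  $p_e = \sum_c p_a(c)\,p_b(c)$ and Cohen's kappa.
* `anova_adjusted_r2()` is the one-way-ANOVA adjusted $R^2$,
  $1 - (1-R^2)(n-1)/(n-k)$, fitted via `stats::lm()`.
* `explained_variation_comparison()` takes, per gene, the difference in
  adjusted $R^2$ between two labelings and averages over genes. The
  bootstrap resamples *genes* with replacement, holding samples fixed: the
  averaged quantity is a mean over genes within a study, so the gene is the
  exchangeable unit. Percentile CIs use the order statistics at ranks
  $\lceil \alpha/2 \cdot B \rceil$ and $\lceil (1-\alpha/2) \cdot B \rceil$
  with $B = 1000$ by default, and are seed-reproducible.
* `weighted_mean_across_studies()` is the study-size-weighted mean,
  $\sum_s e_s n_s / \sum_s n_s$.
* `proportion_from_counts()` renders event counts as percentages with
  round-half-away-from-zero display rounding, the convention of printed
  clinical tables.

# The synthetic cohort generator

`make_reference_cohort()` draws, per sample: a subtype from the configured
frequencies; per-locus copy-number states equal to the subtype archetype
with rare random deviations (rate 0.01 per sample × locus); expression of
each gene as `dosage_effect × state(locus)` plus a subtype-specific basal
shift plus Gaussian noise; and segmented calls on a 22-pseudo-chromosome
genome that encode exactly the locus states used for expression (log ratio
0.5 per state unit), so position-based matching and the
segments-to-expression consistency can be tested end to end.

Default study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_classes` | 10 | the canonical subtype count |
| `class_frequencies` | 0.08, 0.045, 0.15, 0.17, 0.09, 0.065, 0.11, 0.10, 0.07, 0.12 | realistic imbalance; rarest subtype at 4.5% of tumors |
| `n_loci` × `genes_per_locus` | 17 × 36 = 612 | matches the size of a realistic *cis*-eQTL classifier panel |
| `dosage_effect` | 1 (z-score units per state) | a clearly detectable but noise-comparable *cis* effect |
| `basal_shift_sd` | 0.5 | subtype identity is not purely copy-number-driven |
| `noise_sd` | 1 | measurement noise on the scale of the signal |
| `cn_log_ratio_unit` | 0.5 | single-copy gains in log2 ratio territory |

The archetypes (`default_archetypes()`) give each subtype a distinct
gain/loss pattern — one focal-amplification class, one CNA-devoid class —
loosely echoing described breast-cancer biology without claiming fidelity to
real profiles. The `profile_seed` (default 101) fixes the basal profiles
separately from the sampling `seed`, so cohorts drawn with different seeds
come from one reference model; this is what makes
train-on-one-cohort / classify-another meaningful.

`perturb_platform()` emulates an external study: random feature dropout
(e.g. `keep_fraction = 579/612`), per-feature log-normal rescaling and
shifts, and added noise. What the generator does **not** emulate: probe-level
microarray artifacts, count noise of RNA-seq, batch structure, correlated
noise between co-located genes beyond the shared locus state, duplicated
patients across studies, and real-world marginal distributions. Passing
tests on these cohorts therefore demonstrate internal correctness and
robustness to affine platform effects and feature dropout — not performance
on any real cohort.

# Problem sizes used by the tests and the acceptance script

The suite exercises the full default feature panel (612 genes) with cohorts
of 150–2,000 samples where the claim depends on the panel size
(goodness-of-fit null levels, frequency recovery, held-out accuracy), and a
reduced 60-gene geometry elsewhere, where the claim is structural and the
panel size immaterial. The acceptance script trains on a 1,000-sample
reference cohort, classifies a three-study perturbed panel of 100–250
samples each, and uses 1,000 bootstrap replicates for interval estimates —
sizes at which every reported statistic is stable across seeds to well
within its tolerance.

# Known limitations

* Probe-to-gene aggregation by unweighted mean ignores probe quality.
* The diagonal-Gaussian discriminant ignores gene–gene correlation; heavily
  co-amplified regions violate this and are exactly where shrunken offsets
  are largest.
* Within-dataset z-scoring assumes each study's population is comparable to
  the reference population; a study enriched for one subtype shifts its own
  feature means and mildly distorts its z-scores.
* The chance-agreement level of `agreement()` depends on both labelings'
  marginals; comparisons of kappa across classifier pairs with different
  class counts need the reported $p_e$ alongside.
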