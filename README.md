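# nscsubtype

Molecular subtyping of tumor cohorts by nearest shrunken centroids, with
feature matching, cross-platform z-score normalization and centroid
re-estimation for the feature set a study actually provides.

## The problem

Driver-based taxonomies such as the 10-group integrative (IntClust)
classification of breast cancer were derived by clustering matched copy-number
and expression profiles, but most public studies provide expression only, on
heterogeneous platforms with incomplete gene panels. Assigning new tumors to
such subtypes therefore needs a classifier that (i) reconciles a study's
features with the reference panel — by probe name, gene name, or genomic
position for segmented copy-number calls, (ii) puts every study on the
reference scale, and (iii) tolerates missing features by re-estimating its
centroids against the index cohort on whatever features are available. This
package implements that workflow, the per-subtype goodness-of-fit diagnostic
that accompanies it, the comparative statistics used to evaluate competing
classifications (Cohen's kappa, per-gene explained-variation ANOVA with
percentile-bootstrap CIs, study-size-weighted summaries), and a synthetic
cohort simulator so the whole pipeline can be exercised without
controlled-access data.

It is intended for computational biologists who want a transparent,
fully-tested shrunken-centroid subtyper with explicit numerical conventions.

## The model

For feature *j* and class *k* (sizes *n_k*, total *n*, *K* classes) the
classifier computes class centroids x̄_kj, the overall centroid x̄_j, pooled
within-class standard deviations *s_j* with fudge constant *s₀* =
median(*s_j*), and standardized offsets

    d_kj = (x̄_kj − x̄_j) / (m_k (s_j + s₀)),   m_k = √(1/n_k − 1/n)

Offsets are soft-thresholded at Δ, d′_kj = sign(d_kj) max(|d_kj| − Δ, 0),
and centroids rebuilt as x̄′_kj = x̄_j + m_k (s_j + s₀) d′_kj. A sample *x*
is assigned to the class minimizing the discriminant

    δ_k(x) = Σ_j (x_j − x̄′_kj)² / (s_j + s₀)² − 2 log π_k

with posterior probabilities exp(−δ_k/2) / Σ_l exp(−δ_l/2). Δ is chosen by
stratified cross-validation (largest grid value attaining the minimal error —
the sparsest of the best models), reproducibly under a seed. Features a study
lacks are handled by retraining this whole model against the reference cohort
on the available feature subset.

The goodness of fit of a classified study is, per subtype, the Pearson
correlation between the study's subtype-average profile and the training
centroid over the shared features, summarized as the unweighted mean over
non-empty subtypes.

## Worked example

Simulate an index cohort, train a reference, then classify a perturbed
"external study" that provides only 579 of the 612 catalog genes on a
rescaled, noisier platform:

```r
library(nscsubtype)

cfg <- cohort_config(n_samples = 600, seed = 1)
reference_cohort <- make_reference_cohort(cfg)
reference <- train_reference(reference_cohort$expression,
                             reference_cohort$labels,
                             reference_cohort$catalog,
                             reference_cohort$segments)

study_cfg <- cfg; study_cfg$n_samples <- 200L; study_cfg$seed <- 42L
study <- perturb_platform(make_reference_cohort(study_cfg),
                          keep_fraction = 579/612, feature_scale_sd = 0.2,
                          extra_noise_sd = 0.3, seed = 42)

fit <- subtype_cohort(reference, expression = study$expression, seed = 7)
fit
#> Cohort subtyping (expression mode, 579 features)
#>
#>  IC1  IC2  IC3  IC4  IC5  IC6  IC7  IC8  IC9 IC10
#>   19    8   27   32   22   18   19   22   12   21
#> study goodness of fit: 0.912

fit$model
#> Nearest shrunken centroid classifier
#>   classes:  10 (IC1, IC2, IC3, IC4, IC5, ...)
#>   features: 579
#>   samples:  600 (class sizes 40/28/84/95/60/40/74/50/41/88)
#>   threshold: 0.7291 (cross-validated)
#>   features with nonzero shrunken offset: 579

agreement(as.character(fit$result$class), as.character(study$labels))
#> Agreement: 100% observed, 11% expected by chance, kappa = 1 (n = 200)
```

The classifier was re-estimated on the 579 available genes against the
reference cohort, every sample recovered its simulated subtype (kappa = 1
against an 11% chance-agreement baseline), and the study's subtype-average
profiles correlate 0.91 with the training centroids.

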