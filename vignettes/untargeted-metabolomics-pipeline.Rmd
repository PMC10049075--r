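---
title: "Methods: untargeted plasma metabolomics with internal-standard normalization and cross-validated classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted plasma metabolomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Untargeted LC-MS metabolomics of peripheral blood yields a table of ion
features (an m/z value with a retention time, measured in positive or
negative electrospray mode) by samples. In a case-control design — here
modeled on a uveal-melanoma (UM) study with a discovery and a replication
batch, case subclasses defined by the secondary driver mutations *BAP1*,
*SF3B1* and *EIF1AX*, and spiked isotope-labelled standards in every
injection — the analysis must separate three sources of variation:

1. **technical** variation (injection, ionization, storage, batch), which
   the spiked standards measure directly;
2. **disease** signal shared by all cases;
3. **noise**, including below-detection zeros.

The package implements the full protocol: detection filtering,
internal-standard principal-component regression normalization with four
diagnostics, oversampled and noise-regularized random-forest leave-one-out
cross-validation (LOOCV) with bootstrap ROC/AUC, a ten-repeat 50%-subsample
robustness protocol, PCA / t-SNE / PLS-DA embeddings with 95% confidence
ellipses, and a per-feature differential-abundance screen. Because patient
data of this kind cannot be shared, a first-class synthetic-cohort
generator reproduces the statistical structure the protocol assumes, and
every stage is tested against it.

## Data model

A `feature_table` holds a features-by-samples abundance matrix with
per-feature m/z (Th), retention time (s) and one ion mode per table; the
two ion modes are always analyzed as parallel, independent tables over the
same samples. Raw intensities are non-negative with 0 encoding
below-detection; the transform state moves only forward,
`raw -> log1 -> z`. `sample_metadata` carries group, subclass, batch, role
(study / pooled QC / blank / technical replicate), storage time, age, sex,
longest tumor diameter (LTD, mm) and metastasis status. A `standard_set`
names the spiked internal (10 by default) and external (7) standard
features.

## Filtering and transforms

All abundances are first transformed to `log(1 + x)` (natural log), which
maps zeros to zero and makes the multiplicative structure of raw
intensities additive. The detection threshold is the 2nd percentile
(linear-interpolation convention) of the pool of all strictly positive
entries across features and samples; a feature is retained when at least 5
samples lie strictly above that threshold. The threshold is computed per
ion mode and per batch, on the same table being filtered. Standards are
exempt from removal — they must survive to anchor the normalization — and
are flagged when they would otherwise fail. For merged-batch analyses only
features detected in both batches are kept (intersection by feature id),
and the merged table is Z-transformed per feature (population sd; constant
rows map to zeros) before classification or embedding.

Whether the percentile pool should be formed before or after log
transformation is not determined by the protocol description; this package
computes it on the log scale, which is equivalent in rank terms because
`log1p` is strictly monotone — only the reported threshold value differs.

## Internal-standard PC-regression normalization

The centered internal-standard matrix (samples as observations) is reduced
to its first two principal-component score vectors; these summarize the
per-sample technical state. Each feature with at least 75% of samples
above zero is regressed on the two scores, samples with per-feature
|Z| > 3 being excluded from the fit (but still corrected), and replaced by
`residual + feature mean`. Ineligible features keep their log-transformed
values untouched. The regression is ridge-regularized with a
generalized-cross-validation-selected penalty on a grid that includes 0,
so a negligible optimal penalty reduces exactly to ordinary least squares;
the per-feature sample sizes here (tens to low hundreds) almost always put
the selected penalty near zero, and the unit tests pin the OLS limit.

Two open points in the protocol were resolved as follows and are exposed
as the documented behavior: outlier Z-scores are computed on the feature
row *before* fitting (not on fit residuals), and the corrected value
re-centers at the feature mean rather than per batch.

Normalization quality is judged by four diagnostics: the mean
within-batch/total variance ratio (WTR, approaches 1 when batch variation
is gone), the mean pairwise Pearson correlation of pooled-QC profiles, and
two stratified 5-fold cross-validated balanced accuracies of a default
random forest predicting batch and QC-versus-study labels (near 0.5 when
there is nothing to find). Diagnostics whose preconditions fail (a single
batch, fewer than two QC samples) are reported as absent, never as zero.

**Scope of the correction.** Fitted per batch (the default pipeline path),
the regression removes only within-batch technical variation; between-batch
location offsets survive the merge and remain visible in the batch
prediction score. Fitted jointly across both batches
(`norm_scope = "joint"`), the standards' leading component also captures
the batch offset and the regression removes it. The package's positive
control for recoverability (`share_exact` cohorts, where standards are
measured almost noiselessly) uses the joint fit, as does the
differential-abundance calibration: with controls present in only one
batch, any unremoved batch offset is confounded with the case/control
contrast and inflates the per-feature type-I error, which the acceptance
suite demonstrates is cured by the joint fit.

## Classification protocol

The validation engine is a leave-one-out cross-validation around a random
forest of 150 trees with maximum depth 100. For each held-out sample the
training fold is first oversampled with replacement so every class has
exactly 200 rows (each original row kept at least once), then perturbed
with i.i.d. Gaussian noise of sd 0.25 as a regularizer against the exact
duplicates oversampling creates. Both steps happen strictly inside the
training fold: oversampling before the split would duplicate held-out
information into training and inflate the AUC. The held-out class
probability is the fraction of trees voting for each class; argmax ties
resolve to the first class in label order. `N(0, 0.25)` is read as sd
0.25; the `noise_sd` parameter accepts the variance reading (sd 0.5) if
wanted.

Binary tasks report the ROC over positive-class probabilities (positive
class defaults to UM) and the mean and sd of the AUC over 25 bootstrap
resamples of (score, label) pairs; resamples missing a class are redrawn.
The AUC is the trapezoidal area of the tie-grouped ROC, which equals the
Mann-Whitney rank statistic with half-credit for ties — the unit and
acceptance tests pin this equivalence at 1e-12. Robustness is assessed by
repeating the whole LOOCV ten times on fresh draws of 50% of each class
without replacement, summarizing the AUC and per-class F1 ranges.

Technical replicates never inform their source sample's fold:
`loocv_classify` takes a fold-group vector, and all samples sharing the
held-out sample's group leave the fold together.

All randomness descends from one master seed through deterministic tag
hashing (`derive_seed`), so every fold, repeat and bootstrap has an
independent but reproducible stream, and two runs with the same seed are
bitwise identical (single-threaded forests).

## Embeddings

PCA scores (with a deterministic largest-entry-positive sign convention)
and PLS-DA latent variables are computed on the Z-state table. PLS-DA
one-hot encodes the labels and extracts latent directions maximizing the
covariance between projected features and projected labels
(SVD-of-crossproduct with deflation, NIPALS-equivalent); it is treated as
descriptive — a supervised projection separates groups easily, so
cross-validated classification remains the inferential criterion. t-SNE is
an exact O(n^2) implementation (perplexity calibrated by per-point binary
search; early exaggeration and momentum descent), adequate at cohort scale
and reproducible under a fixed seed; it carries structural contracts only,
no geometric claims. Per-group 95% confidence ellipses use the sample mean
and covariance scaled by the chi-square(2 df) quantile 5.991.

## Differential-abundance screen

Per feature: a two-sided Welch t-test of UM versus control study samples
(degenerate features report p = 1 with a flag), and the Pearson
correlation with the longest tumor diameter over UM samples with a
recorded diameter (two-sided p via the t transform). Both p-vectors are
Benjamini-Hochberg adjusted, and features with both adjusted values at or
below alpha are flagged jointly significant. A p-value histogram
diagnostic summarizes calibration: the right tail (p > 0.2) should be flat
(chi-square uniformity statistic; with a few hundred features 10 bins keep
the chi-square approximation honest), with true signal piling up in the
first bin. Welch rather than pooled-variance t is the default because the
group variances are not known to be equal; Pearson on the transformed
scale matches the modeling scale. Both choices are switchable in
principle by operating on the returned p-vectors.

## The synthetic-cohort generator

Per feature j and sample i, on the log scale:

y_ij = mu_j + b_j [batch_i = replication] + delta_j [group_i = UM]
       + s_j shift(subclass_i) + eps_ij,  eps_ij ~ N(0, sigma^2)

with raw abundance `exp(y_ij)`, zeroed with probability `dropout_rate`
(never for standards or pooled QC, which are spiked/pooled well above
detection). Standards carry no group terms but draw batch offsets from
the same distribution as features, so the technical structure is shared;
`share_exact = TRUE` makes standards nearly noiseless, the positive
control under which PC regression can recover the offsets almost exactly.
QC samples are noisy replicates of the pooled mean profile; technical
replicates re-measure a study sample with small technical noise. One
designated feature correlates with LTD at a configurable level.

Defaults are the study conditions the pipeline was designed around:
discovery batch 37/16/15 cases (BAP1/SF3B1/EIF1AX) + 46 controls,
replication 19/17/9; 10 internal + 7 external standards; 200 features per
ion mode of which 40 are informative; sigma = 0.5 with effect_size = 1.0
(Cohen's d = 2, a strong-signal positive control; the real effect sizes of
discriminating plasma metabolites are unknown, so these are stress-test
values, not biology); batch offset sd 0.5; 10% dropout; 6 QC samples and
2 technical replicates; baselines mu_j uniform on log-scale 8-14. Feature
counts are kept at desk scale — hundreds rather than the thousands of a
real untargeted run — which is the problem size used throughout the tests
and the acceptance script.

What the generator deliberately does **not** emulate: retention-time
drift, peak-shape artifacts, isotopes and adducts, correlated metabolite
modules, heavy-tailed noise, or age/sex/storage confounding of the
disease signal. Passing tests therefore demonstrate that the protocol's
machinery behaves as specified under its own assumptions — not that the
headline performance would transfer to real cohorts.

An important structural property is reproduced on purpose: controls exist
only in the discovery batch, so batch and case/control status are
partially confounded, exactly as in the motivating design. The acceptance
suite shows the consequences (inflated per-feature type-I error without
joint batch correction) and that the protocol's own machinery resolves
them.

## Numerical and degenerate-input conventions

- Percentiles: linear interpolation between order statistics (type 7).
- "Above threshold" is strictly greater; the inclusion rule is >= 5
  samples; eligibility is >= 75% of samples above zero.
- Z-transform uses the population (ddof 0) sd; constant rows map to zeros.
- Zero-variance standards: degenerate model with zero scores, a warning,
  and identity normalization.
- Probability ties in argmax go to the first class label; PCA/PLS score
  signs fix the largest-magnitude entry positive.
- Bootstrap sd uses ddof 1; single-resample bootstraps report sd 0.
- p-values of exactly 0 (perfect correlations) are clamped to the smallest
  positive double before BH adjustment, whose domain is (0, 1].

## Known limitations

- The merged-batch default path corrects within-batch variation only; use
  `norm_scope = "joint"` when between-batch offsets must be removed and no
  dedicated cross-batch tool is in play.
- LOOCV AUCs on null data scatter more widely than the i.i.d. Hanley
  formula suggests because held-out scores share training folds; null
  checks in the tests therefore use empirical Monte-Carlo bands.
- t-SNE is exact and quadratic: fine for hundreds of samples, unsuitable
  for thousands.
- The per-feature screen assumes independent features; the generator
  satisfies this, real metabolomes do not.
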