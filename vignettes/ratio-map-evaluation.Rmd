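---
title: "Evaluating derived T1w/T2w map channels for tumor subregion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating derived T1w/T2w map channels for tumor subregion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package operationalizes

Multi-channel segmentation models for brain tumors conventionally take four
co-registered structural MRI contrasts as input: T1-weighted (T1w),
contrast-enhanced T1-weighted (T1w-CE), T2-weighted (T2w) and T2-FLAIR. The
T1w/T2w ratio map — a voxel-wise division of normalized T1w by normalized T2w
intensities, historically used as a proxy for myelin content — sharpens some
tissue contrasts and attenuates shared field inhomogeneities, so it is a
natural candidate for a fifth input channel. Whether that channel actually
*adds* information beyond the four channels it is computed from is an
empirical question, and answering it needs a complete protocol: map
generation, a segmentation model run under each channel configuration, an
overlap metric with careful handling of absent labels, and a paired
statistical comparison.

`ratiomapeval` implements that protocol at desk scale. The deep segmentation
network of a production study is deliberately replaced by a fast,
deterministic per-voxel classifier, and the access-restricted clinical cohort
by a synthetic phantom, so that every stage of the protocol — and the
protocol's own statistical calibration — can be exercised and tested in
minutes on one CPU. The package makes no claim of reproducing any published
Dice level; what it reproduces, and verifies, is the *method*.

## The derived maps

**Ratio map.** Each input is first intensity-normalized: a single Gaussian is
fit (maximum likelihood: sample mean and ML standard deviation) to the voxel
intensities inside the brain mask, and every voxel is divided by twice the
fitted mean, clamping negatives at zero, so the main tissue peak lands at
0.5. With `T1wn` and `T2wn` the normalized images, the map is

$$\mathrm{ratio}(v) \;=\; \frac{T1w_n(v)}{T2w_n(v) + \alpha}.$$

The offset $\alpha$ guards the division. Its default, $10^{-6}$, is the
smallest value that makes the map total without visibly biasing ratios at
the normalized intensity scale (denominators near 0.5); it is exposed in the
configuration. An optional robust fit (trimming to the 1st–99th percentile
range before fitting) is available for volumes whose tumor tails distort the
plain fit; the phantom's brain intensities are symmetric enough that the
plain fit is the default.

**Combined map.** On the *raw* images, with a scaling factor $\beta$ defined
as the ratio of mean ventricle intensity in T1w to that in T2w,

$$\mathrm{combined}(v) \;=\;
  \frac{T1w(v) - \beta\, T2w(v)}{T1w(v) + \beta\, T2w(v)}.$$

Wherever both inputs are nonnegative and the denominator positive the map is
bounded in $[-1, 1]$, and by construction of $\beta$ its mean over the
ventricle is 0. Zero-denominator voxels (both images zero, e.g. background
caught by a loose mask) are set to 0 in-band and counted into the QC output
rather than raised as errors, since they can only occur where there is no
tissue signal. A useful identity both maps inherit: a multiplicative bias
field shared by the two inputs cancels exactly — voxel-wise in the combined
map, and through the normalization constant in the ratio map — which is the
physical motivation for using these contrasts at all. The test suite asserts
the cancellation exactly on phantoms with an injected bias field.

Brain and ventricle masks are *inputs* throughout: in a clinical pipeline
they come from dedicated extraction and subcortical-segmentation tools,
which are out of scope here; the phantom supplies its ground-truth masks. A
crude Otsu-threshold fallback (`brain_mask_from_otsu()`) is provided for
volumes that arrive with no mask at all and is documented as not equivalent
to a dedicated tool.

## The phantom

`phantom_spec()` describes a cohort; `generate_case()` realizes one case
deterministically from `(seed, case_index)`. Geometry: an ellipsoidal brain
(semi-axes 45% of the grid), a small interior ventricle on one side, and on
the opposite side a nested tumor — a non-enhancing core (NET, code 2), an
enhancing rim (ET, code 1), an optional cystic blob inside the core (CC,
code 3) and an optional edema halo outside the rim (ED, code 4) — with
center and radii randomized per case within bounds. A tumor too large to fit
in the brain is an error naming the offending radius, not a silent clip.

Intensities are drawn per tissue class from a configurable table of
per-channel means and SDs. The defaults are invented, qualitatively sensible
values (CSF bright on T2w and suppressed on FLAIR, ET bright on T1w-CE,
edema bright on FLAIR, cyst fluid-like); no claim is made that they match
any real cohort, and every experiment here is a *relative* comparison under
identical conditions, so only the separation structure matters. The
`noise_sd` parameter scales the SD column globally: a voxel's value is
`mean + noise_sd * sd * z` clipped at 0 (magnitude images are nonnegative;
Rician noise is deliberately not modeled), then multiplied by the optional
bias field — a low-frequency cosine with random phase and amplitude
`bias_field_amplitude`. With `noise_sd = 0` every voxel equals its class
mean exactly, which is what makes several exact tests possible:

* the ventricle's T1w mean is derived from its T2w mean and the configured
  `ventricle_t1_t2_ratio`, so the noiseless $\beta$ recovers the configured
  ratio to within floating-point error, and the combined map's ventricle
  mean is 0 to the same precision;
* a noiseless cohort is perfectly separable, so every configuration scores
  Dice 1 on present labels — the harness cannot manufacture differences
  from nothing.

CC and ED presence probabilities default to 0.5 and 0.4, chosen so that
roughly half to two-thirds of cases lack those labels — the same order of
label sparsity that makes censoring and valid-pair counting matter in real
pediatric cohorts. The grid defaults to 64 voxels per axis (written with
1 mm isotropic spacing metadata); tests and the calibration study use 32.

What the phantom does *not* emulate: anatomy (gyri, midline, skull),
partial-volume effects, multi-site batch effects, motion, Rician noise
statistics. Consequently, passing tests here demonstrate correctness and
calibration of the *protocol*, not performance on real MRI.

## The segmenter stand-in

`fit_voxel_classifier()` fits one diagonal-covariance Gaussian per label
class (0 = non-tumor brain, 1–4 = tumor subregions) over the channel
intensities of labeled within-brain voxels, with priors from class counts
and a per-class subsample (default 5000 voxels, seeded) for speed.
`predict_labels()` assigns each within-mask voxel the class with maximal
log-posterior (ties broken toward the lower class code), optionally followed
by majority-vote smoothing in a cubic neighborhood. Numerical choices: class
variances are floored at $10^{-8}$ so noiseless training data remains
well-defined; a class absent from training gets prior 0 and is never
predicted (the uninformative fallback, reported in the model object).

This classifier is *not* a stand-in for the accuracy of a deep network — it
has no spatial context beyond optional smoothing — but it is faithfully
sensitive to the information content of its input channels, which is the
property the comparison harness needs. It is also pluggable: the evaluation
stage accepts any directory of prediction NIfTIs keyed by case id, so
externally produced segmentations can be scored and compared by the same
protocol.

Cross-validation is subject-level: `assign_folds()` partitions cases into
`n_folds` folds (default 5) deterministically given a seed, and each case is
predicted by the model fit on the other folds only — no ensembling, so each
case is scored from its held-out prediction.

## Censored Dice evaluation

For each case, model and label (four subregions plus the composites
TC = ET ∪ NET ∪ CC and WT = TC ∪ ED, formed by binary union on the fly so
they can never drift from their definition), the Dice coefficient
$2|P\cap R|/(|P|+|R|)$ is recorded. When both masks are empty Dice is
defined as 1: the model correctly predicts that there is nothing to segment.
Precisely because such scores say nothing about tissue discrimination,
records with Dice = 1 are censored — removed — before descriptive summaries
and statistical comparisons. The implemented rule censors *every* Dice = 1
record, with the both-empty and exact-match causes recorded in flags
(`pred_empty`, `ref_empty`) so the stricter both-empty-only policy remains
auditable and is available as a configuration switch. Summaries report
mean, SD, median, surviving `n` and the censored count per cell, with and
without censoring; a cell censored down to nothing is reported as `n = 0`
with missing statistics, not an error.

## The comparison protocol

Each augmented configuration is compared with baseline per subregion using a
paired, one-tailed Wilcoxon signed-rank test of the alternative "augmented
exceeds baseline". A case forms a valid pair for a label only if its record
is non-censored under *both* models — censoring is recomputed per
comparison, which is why the number of valid pairs varies across labels and
contrasts. Zero differences are dropped before ranking (the classical
treatment; the count is reported), absolute differences are ranked with
average ranks for ties, and $W$ is the positive-rank sum. The null
distribution is computed exactly — by convolving the characteristic
polynomial of the doubled ranks, equivalent to full sign enumeration — for
up to 25 post-drop pairs, and by a normal approximation with tie and
continuity corrections beyond; realistic cohort sizes land in the
approximation regime while small-sample tests stay exact. All-zero
differences yield a missing result with a recorded reason rather than a
fabricated p-value. Bonferroni control over the four subregions gives the
per-comparison threshold $\alpha_{crit} = 0.05/4 = 0.0125$.

## Calibration of the harness as an instrument

A comparison harness is only trustworthy if it neither finds improvement
where none exists nor misses improvement that does. `channel_validity_study()`
replicates the full experiment — 40-case phantom cohorts at grid 32³ with
`noise_sd = 2` (heavy class overlap, so the baseline is imperfect and
improvement is possible), 5-fold cross-validation, censored scoring, the
signed-rank protocol — under two synthetic fifth channels:

* **pure noise**: an i.i.d. standard-normal field. Across 50 seeded
  replicates, the fraction declaring any subregion a significant improvement
  must stay within the family-wise error budget (≤ 5%).
* **informative**: a field whose mean encodes the reference label
  (0, 12, 24, 36, 48 for classes 0–4, SD 4) — strong but imperfect signal,
  chosen so augmented Dice improves markedly without hitting exactly 1,
  which would be censored away. Detection (some subregion significant) must
  occur in ≥ 90% of replicates.

These problem sizes (32³, 40 cases, 50 replicates per condition) are the
package's chosen operating point for the calibration study: large enough
that ET/NET comparisons carry ~40 valid pairs, small enough that the full
study runs in a few minutes.

One empirical subtlety surfaced by this phantom is worth recording. At
moderate noise without smoothing, the stand-in classifier can segment a
small, well-separated subregion *pixel-perfectly*, producing Dice = 1
records whose masks are not empty; under the "censor all Dice = 1" rule
these are removed alongside the both-empty records, so the censored count
exceeds the count of label-absent cases. With majority-vote smoothing
(radius 1) the classifier behaves like a spatially regularized model:
absent labels give empty predictions, present labels are near- but not
exactly perfect, and the censored records coincide exactly with the
label-absent, empty-prediction cases — the regime the censoring rule is
designed around. The bookkeeping test runs in that regime and additionally
recounts the censored records independently from the saved NIfTI files.

## Orchestration and reproducibility

`run_experiment()` drives the full pipeline from one `experiment_config()`:
cohort generation (NIfTI files plus a CSV manifest), per-case maps with a QC
record (fit means/SDs, $\beta$, zero-denominator counts), one fold
assignment shared by all configurations, per-configuration held-out
predictions, the records CSV, censored and uncensored summaries, the
comparison table, and a run log of every seed and setting. Every stage's
outputs are files, so any stage can be audited or re-scored independently,
and the whole run is bit-reproducible given the configured seeds. The
baseline configuration is mandatory — the comparisons are defined against
it. Training hyperparameters of a deep segmentation framework (epochs,
batch size, optimizers) intentionally have no counterpart in the
configuration: nothing here trains a network.

## Known limitations

* The phantom's geometric and intensity simplicity means absolute Dice
  levels carry no clinical meaning; only within-experiment contrasts do.
* The voxel classifier ignores spatial context (beyond optional smoothing),
  so channel configurations can only differ through per-voxel intensity
  information.
* The signed-rank conventions (zero-difference dropping, positive-rank-sum
  statistic, one-tailed direction "augmented > baseline") are documented
  choices; other software may report the min-sum statistic or handle zeros
  differently, so $W$ values are comparable only within this package.
* Dice is the only metric; surface-distance metrics are out of scope.
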