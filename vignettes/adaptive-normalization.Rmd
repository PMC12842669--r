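---
title: "Adaptive radiograph normalization: model, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive radiograph normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radnorm)
```

## The model

A multi-site chest-radiograph collection mixes images whose intensity
statistics differ for non-diagnostic reasons: detector response, exposure,
vendor display curves. `radnorm` treats this as two separable nuisances:

* **spatial** — lateral background and the neck/shoulder band contribute
  pixels that carry no diagnostic signal but do move global intensity
  statistics; and
* **intensity** — per-site shifts in brightness (additive), contrast
  (multiplicative) and display gamma (nonlinear monotone).

The adaptive pipeline addresses them in order:

1. `cdf_crop()` computes the grayscale-sum profile along each axis,
   normalizes its cumulative sum to a mass CDF, and retains the index set
   `{i : lo < cdf[i] <= hi}` with defaults x ∈ (0.05, 0.95] and
   y ∈ (0.15, 0.95].
2. `histogram_standardize()` applies, on the cropped region, the per-image
   affine map `(I − μ_orig)/σ_orig · σ_target + μ_target` with fixed
   targets μ = 121.788, σ = 57.069 (stored at full precision; displayed
   rounded to 121.8 / 57.1).

Because the map is per-image affine moment matching, it *exactly* cancels
any positive affine intensity change of its input: if two sites differ only
by brightness and contrast, their standardized images are identical. A
gamma difference is not affine, so standardization reduces but cannot
eliminate it — this is the mechanism behind the known failure mode on
heavily heterogeneous collections, and it is visible in the phantom
benchmark (the high-gamma site is aligned in mean and variance but not in
histogram shape).

## Numerical and convention choices

These were genuinely open in the source description; the package fixes them
as follows and isolates each behind one function:

* **"CDF of grayscale-sum values"** is read as the *positional* cumulative
  marginal mass along each axis, not the CDF of sorted sums: cutoff lines
  on a per-axis profile only make sense positionally.
* **Retention rule** `lo < cdf[i] <= hi`, half-open in mass. On a uniform
  image this keeps exactly the central `(hi − lo)` fraction of rows or
  columns — the property that makes "between the 5th and 95th percentile"
  well-defined. Whether the original cutoffs used strict or weak
  inequalities is unknowable from the description; the choice lives
  entirely in `percentile_window()`.
* **Both axis windows come from the original image's profiles**, not
  sequentially re-profiled after the first axis is cut.
* **Degenerate axes fall back to the full extent** and set a flag, rather
  than erroring: a preprocessing library must not crash a batch run on one
  pathological (for example all-black) image. `mass_cdf()` itself still
  errors on an all-zero profile, so the fallback is always an explicit,
  reported decision of `cdf_crop()`.
* **Population (divide-by-N) standard deviation everywhere.** The
  standardization is a moment-matching transform, not an estimator; with
  the sample convention the post-transform moments would not equal the
  targets exactly.
* **Clipping and quantization.** The 0–255 clip happens after the affine
  map; 8-bit outputs round half away from zero. Whether the original
  pipeline clipped is unstated; pre-clip values are available via
  `histogram_standardize(..., clip = FALSE)`, and all moment-recovery
  guarantees are stated pre-clip.
* **Pipeline order** crop → standardize (ROI moments) → resize → quantize.
  Resizing before vs. after normalization was unstated for the adaptive
  arm; standardizing on the un-resized ROI was chosen because bilinear
  resampling slightly shrinks the variance (it averages neighbors), so
  standardizing last would leave a resize-dependent bias in σ.
* **Z-score is dataset-level** (pooled pixels of the training partition),
  matching the benchmark convention being reproduced; a per-image variant
  exists behind `per_image_zscore = TRUE`.
* **Resize** is corner-aligned bilinear (`i · (n_in−1)/(n_out−1)`),
  documented and frozen by closed-form tests.
* **0-based inclusive crop windows** in all public output, reported as
  retained pixel ranges.

## The statistical layer

`wilcoxon_signed_rank()` discards zero differences (classical handling;
the Pratt alternative was rejected to match standard practice and the
n = 12 pairing convention of the reproduced benchmark), midranks ties, and
computes the exact null of `W+` by dynamic-programming convolution over
doubled midranks for `n_effective ≤ 25`. The DP is arithmetically identical
to enumerating all `2^n` sign assignments — including under ties, where it
realizes the permutation distribution over the observed midranks — and the
test suite verifies this against a literal enumeration oracle for all
n ≤ 12. Above the bound, a tie-corrected normal approximation (no
continuity correction) takes over, flagged in the result. Two-sided
p-values are `min(1, 2·min(P(W+ ≤ w), P(W+ ≥ w)))`.

`friedman()` uses the tie-corrected statistic with the asymptotic χ²
reference (k − 1 df). This reference is anti-conservative for very small
block counts (n ≲ 8 with k = 3); exact small-sample tables are documented
as out of scope, and the package's own validation is against the classical
closed form and base R's implementation on tie-free data.

`nemenyi_cd()` embeds the conventional critical values (studentized range
divided by √2, k = 2…10, α ∈ {0.05, 0.10}) rather than recomputing
studentized-range quantiles.

`compare_methods()` chains the three stages with the omnibus gate at
`alpha`. One empirical finding shaped its interface: the published
seed-averaged F1 table of the benchmark this package reproduces, rounded
to two decimals, does *not* yield a significant Friedman statistic — the
published pairwise p-values are only reachable from unrounded per-run
scores that were never printed. Re-deriving those numbers is therefore not
a valid target; the package validates its tests against enumeration
oracles instead, and `posthoc = "always"` lets users produce the full
pairwise report when the omnibus verdict is already known from
finer-grained data. Pairwise p-values are reported raw, as comparison
tables in this literature conventionally do; `holm = TRUE` adds adjusted
values.

## What the phantom emulates — and what it does not

`generate_phantom()` composites a stylized frontal radiograph: dark
background, two bright lung ellipses, a central mediastinal column, a
bright shoulder band across the top rows, a bright sub-diaphragmatic band,
and dim lateral margins. Abnormal images add 1–3 bright opacity disks
inside a lung. Per-site acquisition is modeled as
`clip(gain · 255 · (p/255)^gamma + offset + N(0, σ))`, gamma first because
it stands for the exposure/display curve that precedes linear display
adjustments.

Stated-world defaults, chosen once: 64 × 64 images; three sites —
`site_a` neutral (offset 0, gain 1.0, γ 1.0), `site_b` bright/low-gamma
(+40, 0.9, 0.75), `site_c` dark/high-gamma (−30, 1.15, 1.4) — all with
noise σ = 3. These offsets and gammas are large relative to the lesion
contrast (+55), which is what "strong inter-domain shift" has to mean for
a benchmark whose point is that raw intensity features do not transfer.
Geometry is constrained so the generator's contract holds by construction:
the shoulder band (top 6% of rows) carries ≤ 15% of vertical mass and is
excised by the default crop, lateral margins fall below the 5% horizontal
cutoff, and lesion disks stay inside the lung bounding boxes. Patients
contribute 1–3 images each so patient-level splitting is genuinely
exercised.

What it does **not** emulate: real anatomy (ribs, cardiac silhouette,
costophrenic angles), detector-specific noise spectra, scatter,
positioning variability, pediatric proportions, or label noise. A green
benchmark on the phantom therefore establishes that the pipeline cancels
affine-plus-gamma site shifts well enough for a linear classifier to
transfer — not that any particular accuracy is reachable on clinical data.

## The benchmark harness

`experiment_config()` defaults mirror the reproduced protocol (Adam,
lr 1e-4, batch 100, ≤ 20 epochs, weight decay 1e-5, 80/20 patient-level
stratified split, seeds 42/123/456, cross-entropy, 256 × 256 input). The
optimizer fields parameterize any gradient-trained classifier plugged in
behind `classifier_contract()`; no deep-learning runtime ships here, so
the bundled reference is `classifier_ridge()` — closed-form L2-regularized
least squares on downsampled pixels — which is deterministic, trains in
milliseconds, and deliberately has no internal normalization, so it
transmits whatever intensity shift preprocessing leaves behind.
Augmentation (flip / ±7° / 0.9–1.1 scale / ±5% shift, one bilinear pass,
training images only, never any intensity jitter) is off by default for
the closed-form classifiers and exists for epoch-trained plug-ins.
Validation loss, where reported, is the final-model loss (no early
stopping, matching the plain training loop being emulated). Small datasets
use `min(batch_size, n_train)`.

Two further conventions: dataset-level Z-score statistics are fitted on the
training partition only (asserted by test), and each run's split is
re-drawn from the run's seed, so seed-averaging integrates over both split
and classifier randomness.

## Known limitations

* Standardization assumes the ROI histogram is summarized adequately by
  two moments; bimodal exposure errors or large implants violate this.
* The χ² reference for Friedman at n = 3 blocks (as in the package's own
  3 × 3 examples) is illustrative, not inferential.
* `read_gray()` handles 8-bit PNG/JPEG only; 16-bit radiographs and DICOM
  are out of scope, and JPEG is never written.
* The phantom's lesion contrast is constant across sites; site-dependent
  lesion conspicuity (a real clinical confounder) is not modeled.
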