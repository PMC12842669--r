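# radnorm

Intensity normalization for multi-site chest radiographs, and the machinery
to benchmark whether it helps.

## The problem

Chest X-rays collected at different hospitals differ systematically in
brightness, contrast and display curve: the same anatomy is rendered with
different intensity statistics depending on the detector, the exposure
protocol and the vendor's post-processing. Classifiers trained on one site
routinely degrade on another — a *domain shift* driven largely by these
non-diagnostic intensity differences.

`radnorm` implements an **adaptive preprocessing pipeline** that attacks
both the spatial and the intensity side of this problem, alongside the two
standard baselines, so the three can be compared under controlled
conditions:

1. **Percentile ROI cropping.** Grayscale-sum profiles are computed along
   each axis and converted to mass CDFs; the retained window keeps the
   central 5th–95th percentile of horizontal mass (discarding low-density
   lateral background) and the 15th–95th percentile of vertical mass
   (discarding the bright neck/shoulder band above the clavicle).
2. **Histogram standardization.** On the cropped region, each image is
   mapped by the per-image affine transform

   ```
   I_norm(x, y) = (I(x, y) − μ_orig) / σ_orig · σ_target + μ_target
   ```

   with fixed targets μ_target = 0.4776 · 255 = 121.788 ≈ 121.8 and
   σ_target = 0.2238 · 255 = 57.069 ≈ 57.1, so every image leaves the
   pipeline with identical first and second intensity moments regardless of
   the acquiring site.

Baselines: fixed-range **min–max scaling** (divide by 255) and
**Z-score normalization** using *dataset-level* pooled statistics (fitted on
training pixels only).

Because the package is meant to be testable without any external dataset,
it ships a deterministic **phantom generator** — stylized radiographs (lung
ellipses, mediastinum, shoulder band, lateral margins, optional bright
opacity lesions defining a binary label) pushed through per-site
brightness/gain/gamma/noise transforms — plus a benchmark harness
(patient-level stratified splits, fixed seeds, geometric-only
augmentation, factorial dataset × method × model matrices) and the
non-parametric comparison stack: **Friedman** omnibus test, **Nemenyi**
critical difference, and an **exact Wilcoxon signed-rank** test whose null
distribution is enumerated (via a convolution equivalent to all 2^n sign
assignments) up to n = 25, ties included.

## Worked example

```r
library(radnorm)

# a 3-site phantom dataset: site_a neutral, site_b bright/low-gamma,
# site_c dark/high-gamma
cfg <- phantom_config()
man <- generate_dataset(cfg, n_per_domain = 40, seed = 42, dir = tempfile())

img <- read_gray(man$path[1])
round(c(mean = mean(img), sd = sd(img)), 1)
#>  mean    sd
#>  94.9  68.6

res <- adaptive_normalize(img)
res$crop
#> <crop_result> window x [7, 55], y [6, 60]
round(c(mean = mean(res$image), sd = sd(res$image)), 1)
#> mean   sd
#> 121.8  57.0
```

The crop window (0-based, inclusive) has removed the shoulder band (rows
0–3) and the dim lateral margins; after standardization the image sits at
the target moments (121.8 / 57.1, up to clipping and 8-bit quantization).

Benchmarking under domain shift — train on `site_a` + `site_b`, validate on
the held-out `site_c`, ridge fallback classifier, three seeds:

```r
bench <- domain_shift_benchmark(c("scaling", "adaptive"), classifier_ridge(),
                                n_per_domain = 60, seeds = c(42, 123, 456))
aggregate(cbind(accuracy, f1) ~ method, bench, mean)
#>     method  accuracy        f1
#> 1 adaptive 0.8444444 0.8115337
#> 2  scaling 0.6555556 0.4716546
```

Min–max scaling leaves the site_c intensity shift in the features and the
classifier collapses; adaptive normalization aligns the domains and
recovers most of the lost F1. Method comparison across many
dataset × model blocks then goes through `compare_methods()`, which runs
Friedman → Nemenyi → pairwise exact Wilcoxon and reports raw p-values with
0.05/0.01 verdicts.

## Command line

```sh
Rscript inst/cli/radnorm.R crop --report in.png out.png
Rscript inst/cli/radnorm.R normalize --method adaptive --size 256x256 in.png outdir/
Rscript inst/cli/radnorm.R phantom --n 50 --out phantoms/
Rscript inst/cli/radnorm.R stats --scores results.csv --metric f1 --out report.csv
```

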