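Package: radnorm
Title: Adaptive Intensity Normalization and Benchmarking for Chest Radiographs
Version: 0.1.0
Authors@R:
    person("radnorm", "maintainers", email = "radnorm@example.org", role = c("aut", "cre"))
Description: Tools for preprocessing 8-bit grayscale chest radiographs and for
    benchmarking the effect of intensity normalization on downstream binary
    classification. Implements percentile (mass-CDF) based region-of-interest
    cropping, per-image histogram standardization to fixed target moments,
    min-max and dataset-level Z-score baselines, a deterministic synthetic
    radiograph phantom generator with controllable inter-site domain shift,
    confusion-matrix evaluation metrics, and the Friedman / Nemenyi / exact
    Wilcoxon signed-rank framework for comparing normalization methods across
    dataset-by-model configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
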