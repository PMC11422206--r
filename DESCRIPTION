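Package: nirsvot
Title: Analysis of Muscle NIRS Vascular Occlusion Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying muscle oxygenation responses to cuff-induced
    vascular occlusion and reperfusion measured by continuous-wave
    near-infrared spectroscopy (NIRS). Provides zero-phase low-pass
    conditioning of oxy-/deoxyhemoglobin and tissue saturation index traces,
    baseline normalization, automatic segmentation of occlusion-reperfusion
    cycles (curve onsets, hyperemia spikes, zero crossings, 63% decay points),
    per-cycle hemodynamic feature extraction (extrema, areas under the curve,
    63% time constants, 30-s slopes, post-occlusive reactive hyperemia
    metrics), group-comparison statistics with parametric and non-parametric
    routes and effect sizes, and a synthetic occlusion-response generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
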