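# nirsvot

Analysis of muscle oxygenation responses to cuff-induced vascular occlusion
tests (VOT) measured by continuous-wave near-infrared spectroscopy (NIRS).

During a VOT, a pneumatic cuff interrupts limb blood flow and is then
released. NIRS over the muscle records oxy- and deoxyhemoglobin
concentration changes (O₂Hb, HHb) and the tissue saturation index
TSI = 100·O₂Hb/(O₂Hb+HHb) [%]. Occlusion drives an approximately
exponential desaturation (TSI and O₂Hb fall, HHb rises); deflation produces
a rapid resaturation with a transient overshoot above baseline
(post-occlusive reactive hyperemia, PORH). How large and how fast these
responses are depends on whether the cuff pressure only blocks venous
return (e.g. 50 mmHg) or fully arrests arterial inflow (systolic blood
pressure + 50 mmHg, or an absolute 250 mmHg).

`nirsvot` implements the complete analysis chain for the standard
three-cycle protocol (15-min baseline; three 7-min occlusions interleaved
with 10, 10 and 20-min reperfusions; 10 Hz sampling):

* **Signal conditioning** — 10th-order zero-phase Butterworth low-pass
  (0.8 Hz), baseline normalization over the central ten minutes of the
  baseline (t = 150–750 s), derived TSI and ΔHb = O₂Hb − HHb channels.
* **Segmentation** — deoxy-/reoxygenation curve starts, peaks and ends by
  a scale-free 10% threshold rule; hyperemia spike; nearest zero-crossing
  left of the spike; first 63% decay after it.
* **Per-cycle features** — channel extrema; signed occlusion AUC
  (trapezoid); 63% time constants (τ₆₃); 30-s deoxygenation and
  reoxygenation slopes; PORH maximum, AUC and rise time constant; cycle
  averaging into one value per parameter per session. Plus the
  ankle-brachial screening index.
* **Statistics** — single-pass mean ± 2 SD outlier trimming;
  Shapiro-Wilk/Levene routing between a parametric branch (mixed
  group×session ANOVA, Bonferroni-corrected pooled t-tests, Cohen's d) and
  a non-parametric branch (Kruskal-Wallis, Dunn's post hoc, rank-biserial
  correlation r = 1 − 2U/(n₁n₂)).
* **Synthetic cohorts** — a generator with logistic pressure-to-occlusion
  coupling c = 1/(1+e^(−(P−SBP)/k)), exponential kinetics, an
  alpha-function hyperemic overshoot, noise and drift, plus closed-form
  ground truth for every extracted feature, so the whole pipeline is
  testable without participant data.

See `vignettes/nirsvot-methods.Rmd` for the model, parameter defaults and
validation strategy.

## Worked example

```r
library(nirsvot)

co   <- simulate_cohort(list(G1 = list(rule = 50,       n = 4),
                             G2 = list(rule = "SBP+50", n = 4)),
                        seed = 42)
cfg  <- pipeline_config()
summ <- run_extract(co, cfg)
summ[1:4, c("subject_id","group","session","cuff_pressure",
            "tsi_min","hhb_max","hhb_tau","tsi_max_porh")]
#>   subject_id group session cuff_pressure tsi_min hhb_max hhb_tau tsi_max_porh
#> 1        S01    G1      S1            50  -19.61   17.55   131.2       0.7123
#> 2        S01    G1      S2            50  -20.09   16.96   131.4       0.6708
#> 3        S02    G1      S1            50  -18.83   15.99   135.8       1.1291
#> 4        S02    G1      S2            50  -19.75   15.95   132.5       1.0143
```

Each row is one subject-session: `tsi_min` is the deepest desaturation
(percent below baseline) during occlusion, `hhb_max` the HHb rise (device
units), `hhb_tau` the time (s) to 63% of that rise, and `tsi_max_porh` the
hyperemic overshoot above baseline — near zero for the venous-only group.

```r
res <- run_stats(summ, cfg, parameters = c("tsi_min", "hhb_tau"))
res$table[res$table$Session == "S1",
          c("Variable","A","B","A_mean","B_mean","p_corrected",
            "effect_size","effect_kind")]
#>  Variable  A  B A_mean B_mean p_corrected effect_size   effect_kind
#>   tsi_min G1 G2  -19.5  -29.8    1.06e-06      14.045       cohen_d
#>   hhb_tau G1 G2  134.0  135.6    7.73e-01      -0.125 rank_biserial
```

The suprasystolic group desaturates ~10 percentage points deeper than the
venous-only group (corrected p < 0.001, very large effect), while the
63% time constant does not differ — in this synthetic cohort both groups
share the same programmed deoxygenation kinetics, so only
amplitude-driven parameters separate.

A command-line front-end (`inst/cli/nirsvot.R`) exposes `simulate`,
`extract`, `stats` and `report` subcommands over YAML configurations.

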