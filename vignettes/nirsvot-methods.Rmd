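---
title: "Quantifying muscle NIRS occlusion-reperfusion responses with nirsvot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle NIRS occlusion-reperfusion responses with nirsvot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsvot)
```

## The measurement problem

A vascular occlusion test (VOT) inflates a pneumatic cuff around a limb,
interrupting blood flow, and then releases it. Continuous-wave near-infrared
spectroscopy (NIRS) placed over a muscle tracks the resulting concentration
changes of oxygenated and deoxygenated hemoglobin (O2Hb, HHb; device units)
and the tissue saturation index,

TSI = 100 * O2Hb / (O2Hb + HHb)  [%],

which summarizes the balance between oxygen supply and consumption. During
occlusion the muscle consumes oxygen without resupply: TSI and O2Hb fall,
HHb rises, each approximately exponentially. On deflation, flow resumes and
transiently overshoots — post-occlusive reactive hyperemia (PORH) — before
settling back to baseline. The magnitude and speed of both limbs of this
response carry physiological information (training status, microvascular
function) and depend on the applied cuff pressure: a low pressure occludes
only venous return, while pressures well above systolic blood pressure
(SBP) arrest arterial inflow completely.

`nirsvot` implements the full analysis chain for the standard three-cycle
protocol: a 15-min baseline, then three 7-min occlusions interleaved with
reperfusions of 10, 10 and 20 min (4560 s in total), sampled at 10 Hz, with
three pressure groups — 50 mmHg (venous-only), SBP + 50 mmHg
(individualized), and 250 mmHg (absolute).

## Signal conditioning

Channels are smoothed with a 10th-order low-pass Butterworth filter
(cutoff 0.8 Hz) applied forward and backward (`lowpass_zero_phase()`),
which cancels the group delay exactly and squares the magnitude response.
"10th order" refers to the designed one-pass filter; the effective
magnitude is that of a 20th-order response. Forward-backward filtering is
sensitive to edge transients, so each channel is extended by odd reflection
before filtering. We use a 200-sample pad (20 s at 10 Hz): shorter pads of
a few filter lengths leave visible (~0.5%) transients at this low
normalized cutoff, while 200 samples push the residual error on a constant
signal below 1e-7.

All channels, TSI included, are then expressed as magnitude differences
from rest by subtracting the mean over the central ten minutes of the
baseline, t in [150, 750) s (`normalize_to_baseline()`). Normalizing twice
is a contract violation and raises an error. The hemoglobin difference
dHb = O2Hb − HHb is formed after normalization (the two operations
commute). If an input file lacks a device TSI column, TSI is derived from
the concentration channels via the definition above; a spatially resolved
device TSI is preferred when present because it is not reconstructible from
concentration changes alone. Gaps of at most 0.5 s are bridged by linear
interpolation (filtering requires a uniform grid); longer gaps fail the
recording.

Concentration units are carried opaquely as device units throughout; no
unit conversion is attempted.

## Segmentation and features

Within each cycle the deoxygenation and reoxygenation curves are located by
a scale-free 10% rule (`detect_curve_bounds()`): the curve peak is the
sample of largest absolute deviation from the local pre-event level (the
first sample of the search window), the start is the last time before the
peak at which the deviation is within 10% of the peak deviation, and the
end the first such time after it (window end if the signal never returns —
a plateau). Search windows are offset by the cuff ramp time (default 6 s,
matching the 5-8 s inflation/deflation of a manual cuff). Ties at equal
extrema break to the earliest time, for determinism.

Per cycle and channel the package computes:

* extrema over the full occlusion + reperfusion cycle;
* the signed occlusion AUC — the trapezoidal integral of the normalized
  signal over the occlusion window. The sign is retained (negative for TSI
  and O2Hb during deoxygenation), since it is the deviation from baseline
  that is integrated;
* the 63% time constant: elapsed time from the (ramp-offset) occlusion
  start until the signal first attains 63% of its extreme deviation in the
  window, with linear interpolation between samples. HHb is tracked upward;
  TSI, O2Hb and dHb downward;
* 30-s deoxygenation and reoxygenation slopes: OLS fits over the first
  30 s after the detected curve starts;
* TSI hyperemia metrics: the spike (global maximum within the first 120 s
  of reperfusion), the PORH AUC integrated from the zero-crossing nearest
  the spike on its left to the first 63% decay of the spike amplitude after
  it, and a PORH rise time constant measured from the reoxygenation curve
  start to 63% of the spike value. The left-crossing convention bounds the
  reoxygenation area from below; the 63% decay endpoint is used because
  repeated occlusions can leave oxygenation elevated above baseline, so a
  return-to-zero endpoint would be ill-defined.

A spike that never exceeds zero is flagged "no hyperemia" — the expected
outcome for venous-only pressures — and the PORH quantities are left
missing. The three cycles are averaged (unweighted) into one value per
parameter per session, over the non-flagged cycles only.

## Statistics

Group comparisons follow a two-route design per parameter and session.
First a single-pass outlier rule drops values outside mean ± 2 SD (sample
SD, computed once on the full input per group and session — iterating the
rule would remove additional points the rule does not define). Shapiro-Wilk
normality per group and Levene's variance homogeneity (mean-centered)
choose the route at alpha = 0.05: parametric (mixed group-by-session ANOVA
via `aov` with an `Error(subject/session)` stratum, pooled-variance
pairwise t-tests, Cohen's d with the two-group pooled SD) or non-parametric
(per-session Kruskal-Wallis with tie correction, Dunn's z tests on pooled
mid-ranks, rank-biserial correlation). All pairwise p-values are Bonferroni
multiplied and capped at 1. With two sessions the sphericity condition
holds trivially and is reported as such. Cohen's d accepts an externally
supplied pooled SD for users who prefer a design-wide error term; the
magnitude labels use the conventional ascending 0.2/0.5/0.8 thresholds.
The rank-biserial correlation is computed in its dominance form
r = (#(a>b) − #(a<b)) / (n_a n_b), which equals 2U_a/(n_a n_b) − 1 with
mid-rank tie handling and is ±1 at complete separation.

No pre-installed package provides Dunn's post hoc, so it is implemented
directly (tie-corrected pooled-rank variance); all other tests are standard
library calls.

## The synthetic generator

Real participant recordings are not bundled; instead `simulate_session()`
and `simulate_cohort()` generate recordings with the statistical and
kinetic structure the analysis assumes, plus exact ground truth, making
every downstream stage testable. The generator is phenomenological, not a
mechanistic circulation model, and its equations are artifact choices of
this package:

* **Occlusion completeness.** c = 1/(1 + exp(−(P − SBP)/k)) interpolates
  smoothly between venous-only (c ≈ 0) and complete occlusion (c ≈ 1),
  with c = 0.5 at P = SBP and width k = 10 mmHg by default.
* **Deoxygenation.** HHb rises as A(1 − e^(−t/τ_deoxy)) with
  A = a_ven + c·a_art; O2Hb mirrors it with negative sign. Defaults
  a_ven = 18, a_art = 10 device units and τ_deoxy = 150 s place the
  suprasystolic HHb amplitude near 28 units and the extracted 63% time
  constant near 134 s, in the physiological range for resting forearm
  muscle.
* **TSI from pools.** TSI is computed from absolute pools
  (baseline 65% of an 88-unit total), so the suprasystolic TSI excursion
  is about −32%, and TSI remains within [0, 100] by construction.
* **Reperfusion and PORH.** Deviations wash out exponentially
  (τ_reoxy = 8 s) and a single-peak alpha-function pulse
  (t/t_p)e^(1−t/t_p) with t_p = 30 s moves hemoglobin from the
  deoxygenated to the oxygenated pool (an arterial-inflow exchange, total
  hemoglobin unchanged), scaled by completeness. This produces a TSI spike
  of about +10% for complete occlusions, essentially none for venous-only
  pressure, and a transient HHb undershoot. An additive-pool overshoot was
  rejected: inflating total hemoglobin dilutes TSI and cannot produce the
  observed spike without unrealistic (>30%) volume excursions.
* **Nuisance structure.** Cuff inflation/deflation is a 6-s linear
  amplitude ramp. Per-channel white Gaussian noise (SD 0.6 units, chosen
  so the baseline TSI SD is ~0.5%, plausible for this device class),
  per-channel linear drift with rate drawn uniformly within
  ±0.001 units/s per session, and a per-subject-session baseline offset
  (SD 1 unit) emulating optode repositioning between visits. Cohort SBP
  is drawn from Normal(118, 9) mmHg.

What the generator does **not** emulate: venous pooling (real venous-only
occlusion raises both O2Hb and HHb, whereas the mirrored model lowers
O2Hb), adipose-tissue optics, movement artifacts, slow autonomic
oscillations, or any mechanistic PORH pathway. Passing recovery tests on
synthetic data therefore demonstrates the correctness of the measurement
operators under the stated signal model, not validity on arbitrary real
recordings.

## Validation strategy and numerical choices

Ground truth for every extracted feature is derived from the continuous
cycle model by root finding (`uniroot`), golden-section optimization and
quadrature — a code path fully independent of the sampled-signal
extraction. On noiseless cohorts the two agree to within one sample
(0.1 s) on every event time and within 0.1% on every resolvable amplitude.
Two deliberate details:

* Oracle-equivalence checks run the extraction on unfiltered noiseless
  recordings. The low-pass filter smooths the slope discontinuities at
  cuff transitions and would contribute its own (documented, ~1%)
  distortion to steep reoxygenation slopes; its contract is tested
  separately against the analytic Butterworth magnitude response.
* The 30-s slope oracle evaluates the model on the 10 Hz acquisition grid
  before fitting: at this rate the discrete OLS slope of a steep
  exponential differs from the continuous-time slope by ~0.2%, a property
  of the estimator, not an implementation error.

Recovery under the default noise uses 100 replicates of a full
suprasystolic session; each parameter's mean lands within 5% of truth
(worst case ~4%, the positive bias of extrema of noisy signals). Type-I
calibration uses 1000 null cohorts (12 subjects per group, two sessions)
through the mixed ANOVA, and the three-group separation pattern (venous
group different from both suprasystolic groups, which do not differ) is
checked over 200 replicates at a programmed 3-SD standardized difference.
Problem sizes were chosen so the whole validation suite completes in about
a minute of CPU.

Degenerate inputs are contracts, not crashes: flat windows yield "no
event", a spike at or below zero yields "no hyperemia", a series that
never returns below threshold ends at the window end, a missing
zero-crossing falls back to the window start with a warning, zero-variance
groups force the non-parametric route, and all-flagged parameters stay
missing through averaging.

## Known limitations

* The 63% PORH rise time constant is one of several defensible readings of
  a "PORH time constant"; it is implemented as the time from the detected
  reoxygenation start to 63% of the spike value and labelled as such.
* Cohen's d from the two-group pooled SD will not reproduce d values
  computed by factorial-ANOVA software from a design-wide error term;
  supply `sd_pool` to match such conventions.
* dHb time constants are computed and exposed but have no established
  reporting convention.
* The simulator's venous-only regime underestimates the O2Hb excursion
  structure of real venous pooling (see above); venous-group features
  other than HHb-driven ones should not be over-interpreted on synthetic
  data.
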