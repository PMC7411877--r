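---
title: "HRV monitoring and preictal warning with multivariate SPC"
author: "hrvmspc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV monitoring and preictal warning with multivariate SPC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvmspc)
```

## The problem and the model

Seizures perturb the central autonomic network, and the perturbation is
visible in heart rate variability (HRV) minutes before clinical onset.
A wearable warning system therefore needs four things working together
on a beat-to-beat R-R interval (RRI) stream: artifact-tolerant interval
cleaning, HRV feature extraction at beat cadence, a statistical notion of
"normal for this person", and an alarm rule robust to momentary
excursions. This vignette documents how each part is modelled here, which
knobs matter, and what the synthetic validation does and does not show.

### Streaming RRI cleaning

Each incoming interval is screened against the trailing 180-s
first-in-first-out buffer of accepted intervals. With the buffer median
and the median absolute deviation (MAD), the robust spread is
`sigma = 1.4826 * MAD`, and intervals outside `median ± 4 sigma` are
outliers. Short outliers are ectopy-like and removed. A long outlier is
read as `N = round(RRI / median)` missed beats and replaced with `N`
copies of `RRI / N`, conserving summed beat time exactly — this matters
because the frequency-domain indices are computed on the beat-time axis.

Decisions the procedure itself does not pin down, made here as package
policy:

* **Warm-up.** Screening starts once the buffer spans 30 s
  (configurable); earlier beats pass through as `measured`. Screening a
  nearly empty buffer would make the MAD meaningless.
* **Candidate exclusion.** The buffer statistics exclude the candidate
  interval itself (the buffer holds only previously accepted beats).
* **Bound equality.** The acceptance band is open: equality with a bound
  classifies as the adjacent outlier class. Conservative, and a
  measure-zero event for real data.
* **Corrected beats re-enter the buffer**; removed beats never do, so a
  run of ectopy cannot drag the median.
* **Degenerate buffer** (constant intervals, `sigma = 0`): the band
  collapses, so intervals within ±20% of the median are accepted and
  anything else classified by sign. A pathological but valid constant
  stream should not reject every subsequent beat.
* **Time accounting.** Cleaned beat times are the cumulative sum of
  accepted intervals: corrections leave elapsed time unchanged, removals
  shorten it. With realistic removal rates (<1% of beats) the drift is
  small relative to the 15-min evaluation horizon, but it is the reason
  the cohort experiment below injects anomalies into artifact-free
  streams: ground-truth windows then align exactly.

### HRV indices

Eight indices per 3-min window, in fixed order: meanNN, SDNN, RMSSD,
NN50, TP, LF, HF, LF/HF. Time-domain indices come straight from the
windowed intervals; NN50 counts adjacent pairs differing strictly more
than 50 ms. SDNN uses the population divisor `n` by default (the same
convention the failure-rate summary uses), with the sample divisor as an
option.

For the frequency domain the tachogram is resampled at 4 Hz with a cubic
spline (evaluated only inside the knot range — no extrapolation), the
mean is removed, and an AR(40) spectrum is fitted. Burg estimation is
the default: it is the standard choice for short HRV windows, where
Yule-Walker's taper bias is visible; Yule-Walker remains available as a
config option. The one-sided density is evaluated on 1024 grid points
over [0, 2 Hz] and integrated by the trapezoid rule with interpolated
band edges: LF over 0.04–0.15 Hz, HF over 0.15–0.4 Hz.

Two ambiguities worth knowing about:

* **Total power.** "Total power, variance of RRI" can be read as the PSD
  integral or the time-domain variance. The default is the PSD integral
  over 0–0.4 Hz (DC excluded by mean removal); `tp_mode = "variance"`
  switches to the windowed population variance. The two differ by
  spectral mass above 0.4 Hz and by resampling error.
* **LF/HF with HF = 0.** A constant window has no spectral power; the
  ratio is reported as a configurable sentinel cap (default `1e6`)
  rather than `Inf` or an error, so downstream autoscaling stays finite.

### MSPC: Q and T² with empirical limits

The eight indices have incommensurate units (ms, ms², counts, a ratio),
so the monitored vector is autoscaled with the training mean and SD
before anything else — the monitoring statistics are defined on the
scaled vector. PCA of the training correlation matrix retains the six
leading components: `V_R` (8×6, orthonormal) and the score standard
deviations `Σ_R`. Then

* `Q = xᵀ(I − V_R V_Rᵀ)x` — the squared residual off the model plane;
  it fires when the *correlation structure* among indices breaks;
* `T² = xᵀ V_R Σ_R⁻² V_Rᵀ x` — the Mahalanobis distance within the
  plane; it fires on unusual *excursions along* modelled directions.

Loadings follow a deterministic sign convention (largest-magnitude
element positive) so model files are reproducible; models round-trip
through JSON bit-exactly (17 significant digits).

Control limits are one-sided upper empirical percentiles (linear
interpolation between order statistics, R type 7) of normal-condition
statistics at `alpha = 99%`. For nonnegative statistics a two-sided
confidence band makes little sense; the one-sided upper limit is
standard MSPC practice. The two-level scheme — one global model, one
control-limit tuning per subject — is supported by keeping `fit_mspc()`
and `tune_control_limits()` separate; no transform is applied to NN50 or
LF/HF before PCA.

### The alarm state machine

Per beat, with `y` the interval in seconds: while the exceedance
condition pushes toward a state change (exceedance while interictal,
recovery while preictal), the counter `tau` accumulates `y`; otherwise
it resets to zero. At `tau ≥ 10 s` the status toggles and `tau` resets.
Equality with a control limit counts as non-exceedance ("exceeds" is
strict).

The recovery condition is implemented as the logical negation of the
exceedance condition, so the machine is a clean two-state debouncer. The
alternative literal reading — recover when *either* statistic is at or
below its limit — would let one quiet statistic clear a warning while
the other still exceeds, and produces re-arming ping-pong; it is
available as `recovery = "literal"` and covered by a test. Modes `q`,
`t2` (the default analysis runs both in parallel, matching how the two
statistics are reported separately) and `either` (the combined rule) are
all supported.

### Evaluation conventions

All intervals are half-open `[start, end)`. A seizure counts as
predicted when any alarm episode overlaps `[onset − 900 s, onset)` — any
nonempty intersection counts, and several episodes before one onset
count once. The false-positive rate attributes an episode to interictal
time by its onset and divides by total interictal hours. Sign tests are
exact binomial tails; group FP rates are compared with Welch's t-test
(the equal-variance test is an option). Bland–Altman agreement reports
the mean difference and `bias ± 1.96 SD` limits. Failure-rate summaries
round per-subject percentages to one decimal and summarize the rounded
values with the population-SD convention, which is how such tables are
printed.

## The synthetic generator

`generate_interictal()` emits beats iteratively from an instantaneous
interval function: baseline plus a 0.10-Hz and a 0.25-Hz sinusoid plus
white Gaussian noise, each beat's interval read off at the current
cumulative time (a lightweight stand-in for integral pulse-frequency
modulation). Defaults — 900 ms baseline, 35/25 ms amplitudes, 15 ms
noise — give resting-adult index values (SDNN ≈ 35 ms, LF/HF ≈ 1.5).
Artifacts: a missed beat merges two adjacent intervals (high outlier),
an ectopic event splits one interval ~35/65 (low outlier); ground truth
is returned for scoring. A preictal anomaly re-emits the stream from its
stored seed with parameters shifted inside the window: baseline ×0.88
(heart-rate acceleration), LF ×2.2, HF ×0.35 (sympathovagal shift),
noise ×1.8, and a 0.6 rotation mixing the band amplitudes so the
*correlation structure* changes, not just the level. This effect size is
a frozen package constant chosen during development so that end-to-end
recovery passes with margin; it is a validation fixture, not a clinical
claim.

What the generator does **not** emulate: circadian and sleep-stage
drift, respiration-rate wander, true ectopic morphology, movement
artifacts, or any pathological preictal signature. Passing the synthetic
validation therefore shows the *machinery* is correct and calibrated —
it says nothing about clinical sensitivity on real patients.

## The cohort experiment

`cohort_experiment()` is the package's end-to-end validation: seven
subjects with different baselines/amplitudes/noise, each 21.8 h of
synthetic data — 3 h for fitting the global 6-component model (pooled
across subjects), 12 h for per-subject control-limit tuning, 6 h held
out for calibration measurement, then two 5-min anomalies whose ends
mark seizure onsets. Streams are cleaned, HRV vectors extracted every
10th beat (~9 s), and the `either`-mode alarm machine is scored against
the truth intervals and the 15-min horizon.

The segment lengths are deliberately long, and that is a statistical
necessity rather than generosity: consecutive sliding windows share
almost all their beats, so monitoring statistics are strongly
autocorrelated and held-out exceedances arrive in bursts comparable to
the window span. The effective sample size of an exceedance-rate
estimate is set by burst count, not vector count; likewise a 99th
percentile tuned on a short segment is noisy, and because the tail
function is convex, percentile noise systematically inflates held-out
exceedance. With 12-h tuning and 6-h held-out segments per subject the
pooled held-out exceedance of each statistic concentrates near the
nominal 1% (the acceptance suite asserts 0.5–1.5%), and every injected
anomaly is detected with no false episode needed to do so.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (type 7).
* Band integrals: trapezoid rule, PSD interpolated at band edges.
* AR fit: fixed order 40, mean removed first; a constant (zero-variance)
  resampled series yields an identically zero density rather than an
  error.
* `round()` in missed-beat estimation is R's round-half-even; half
  values are measure-zero for real intervals.
* Zero-variance training columns abort the fit with the column named;
  a zero score SD aborts T².
* Random streams derive from one seeded generator per call
  (`withr::with_seed`), never from global state; equal seeds give
  byte-identical output files.

## Known limitations

* The cleaned time axis contracts at removals (see above); wall-clock
  alignment of episodes against external labels degrades with the
  removal rate.
* The AR(40)/4-Hz spectrum resolves the standard LF/HF bands but not
  very-low-frequency structure; windows shorter than ~3 min starve the
  fit (the resampled series must exceed the model order).
* Exceedance-rate validation at α = 99% needs hours of interictal data
  per subject; with short records the empirical control limit is
  unreliable — the same caveat applies to any per-subject tuning on
  sparse clinical interictal data.
* The generator's anomalies are one fixed effect family; detection rates
  on them do not transfer to clinical preictal physiology.
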