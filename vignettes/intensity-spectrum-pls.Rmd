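---
title: "Methods: from raw acceleration to selectivity-ratio spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw acceleration to selectivity-ratio spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelspec)
```

This vignette is the package's account of its methods: the processing model
and its assumptions, the parameters that matter, the design decisions taken
where the method leaves room, and the limits of what the synthetic tests
demonstrate.

## 1. Why two frequency bands

Hip-worn accelerometers capture body acceleration whose dominant frequency
is the step frequency, roughly 1.4 Hz in slow walking up to about 3.5 Hz in
fast running. A processing chain that low-pass filters at 1.6 Hz (the
classical ActiGraph-style band, the `"ag"` arm here) therefore attenuates
exactly the content that grows with intensity: its epoch output rises with
walking speed, plateaus near the walk–run transition, and falls again at
higher running speeds. A 10 Hz low-pass corner (the `"wide"` arm) keeps all
frequency content of human movement, so output remains monotone in
intensity. The package implements both arms so that their downstream
associations with health can be compared on identical data.

## 2. Signal processing

**Filter.** Both arms are Butterworth band-passes sharing a gravity-removal
(high-pass) corner at 0.29 Hz, with low-pass corners of 1.6 Hz (`ag`) and
10 Hz (`wide`). We use `signal::butter(2, ..., type = "pass")`, a 4th-order
band-pass (two poles per edge), so each corner is the half-power point of
the single-pass response. Filtering is applied forward–backward (zero
phase); the effective amplitude response is the squared magnitude, reported
by `filter_gain()`. End effects are controlled with 10-s odd (reflect and
invert) extensions, long enough for the slow 0.29 Hz pole to settle.

Numerically relevant consequences:

- the zero-phase AG gain at 3 Hz is below 4% of its passband gain, which is
  the mechanism of interest, and
- zero-phase application attenuates roughly twice as much (in dB) above the
  corner as a single-pass chain would. The true ActiGraph count chain
  (resampling, dead-band, quantization, single-pass filtering) is *not*
  emulated; the AG arm emulates its frequency band only. Comparisons with
  literature count values should keep this in mind.

**Epochs.** Each axis is filtered independently; per sample the Euclidean
norm of the three filtered axes is taken, and per non-overlapping 3-s
window (90 samples at 30 Hz) the mean norm is reported in mg. Norm after
filtering was chosen for rotation robustness; trailing partial epochs are
dropped, never padded; samples are clipped to the ±6 g device range on
ingest. The whole chain is homogeneous: scaling the raw signal scales every
epoch value identically.

## 3. Wear validity

Night time (epochs starting in 00:00–06:00, half-open) is removed first, so
wear statistics refer to the 06:00–24:00 span. Non-wear is then a run of at
least 60 min of zero epochs — "zero" meaning ≤ 10⁻⁶ mg, since exact zeros
are measure-zero after filtering — with a cumulative allowance of up to
2 min of output strictly between zero and the sedentary threshold
(19.1 mg). An epoch at or above the threshold terminates the window;
allowance epochs may sit at window edges; candidate windows never span gaps
in the epoch timeline, which makes detection invariant to concatenating
disjoint days. Detection always runs on the AG arm, and the resulting mask
is applied unchanged to the wide arm of the same subject, so wear time is
identical between arms by construction.

A day is valid with ≥ 8 h of wear (strict: 7.99 h fails), a measurement
with ≥ 4 valid days. All thresholds are parameters of `accel_config()`.

## 4. The intensity spectrum

Wear epochs on valid days are assigned to half-open bins by value; counts
× 3 s, divided by the number of valid days, give minutes/day. The AG scheme
has edges 0, 10, 20, 40, 60, … (+20 mg); the wide scheme 0, 40, 80, 160,
240, … (+80 mg) — four times the AG edges, since the wide output runs about
four times higher at high intensity. The first two bins are half width so
that the sedentary and light ranges are resolved; the last bin is open to
infinity so no epoch is discarded, and the bin minutes of every subject sum
*exactly* to mean daily wear minutes. The default of 22 bins is a
configuration parameter, not an algorithmic constant: in cohort work the
usable number of bins is where association runs out, which is
data-dependent. MET-anchored cut-points (1.5/3/6/9 MET equivalents:
19.1/63.0/171.0/300.2 mg AG, 38.9/167.2/582.3/994.1 mg wide) provide the
conventional SED/LPA/MPA/VPA/VVPA coarsening; classes are half-open like
the bins, and class minutes conserve the same total.

## 5. The composite score

Six markers enter: systolic blood pressure (mmHg), triglycerides (mmol/L),
total cholesterol:HDL ratio, HOMA, waist:height ratio, and
cardiorespiratory fitness (mL/kg/min). HOMA is computed as
glucose (mmol/L) × insulin (pmol/L) / 22.5, exactly as defined for this
composite. Note the unit: the classical HOMA-IR formula takes insulin in
µU/mL (1 µU/mL = 6 pmol/L), so this index is a constant multiple of the
classical one; because every marker is z-standardized before averaging, the
constant cancels and the composite is unaffected. The classical variant is
available via `insulin_unit = "uU/mL"` but is off by default — the formula
is implemented as defined, not silently "corrected".

All markers except fitness are risk markers and are negated before
standardization, so higher always means healthier. Standardization uses the
sample (n−1) SD; the composite is the mean of the six standardized values;
subjects with any missing marker are excluded (complete case). The
composite has cohort mean zero by construction and is invariant to affine
unit changes of any marker.

## 6. The association model

**PLS.** Time-in-bin variables are strongly collinear (neighbouring bins,
and the sedentary/active trade-off), so multiple regression is unstable.
NIPALS PLS with a univariate response extracts components that maximize
covariance with the composite score; all predictors and the response are
standardized first. If the residual covariance vanishes, extraction stops
and remaining coefficients are zero. Columns with zero variance are kept as
all-zero standardized columns with zero coefficients, so bin bookkeeping
never shifts.

**Component count.** 100 Monte Carlo half-splits: fit on a random half
(standardization statistics recomputed inside the half — no leakage),
RMSE on the held-out half, choose the count with the lowest median RMSE.
The held-out evaluation is a deliberate choice: in-sample RMSE decreases
monotonically in the component count and cannot select. Ties (exactly equal
medians) resolve to the smaller count via `which.min`. One property of
strict minimum-RMSE selection is worth knowing: with *independent*
predictors and a strong single-variable signal, the first PLS weight vector
carries sample cross-covariances whose out-of-sample cost exceeds the
overfitting cost of further components, so more than one component is
systematically chosen even when the truth is one-dimensional. In the
collinear regime of intensity spectra — a latent activity factor driving
many correlated bins — the parsimonious count is recovered almost always,
and that is the regime the selector is used in here.

**Target projection and selectivity ratios.** The fitted model is collapsed
onto the direction of its regression vector; predictions are unchanged
(this is checked to 10⁻⁸ in the tests). Per bin, the selectivity ratio is
explained over residual variance on that single predictive component,
signed by the target-projection loading. A bin perfectly explained returns
a signed `Inf` sentinel; an all-zero bin returns 0.

**Confidence intervals.** The same resampling draws (at the chosen count)
provide 95% percentile intervals — linear interpolation between order
statistics (`stats::quantile` type 7) — for every bin's SR and for R². Each
draw's SR signs are aligned to the full-data orientation before taking
percentiles, guarding against component sign flips across draws. The R²
point estimate is the in-sample explained variance of the full-data fit at
the chosen count; its CI uses the training-half in-sample R² draws, which
estimate the same quantity. Held-out R² draws are recorded separately —
they are the quantity that must sit near zero when no effect exists, and
the null-calibration checks use them.

## 7. The synthetic cohort generators

No cohort data ship with the package; two generators provide ground truth.

**Single-arm cohorts** (`simulate_cohort()`): daily wear time
N(14.1 h, 1.3 h) truncated to 10–18 h; active bins get log-normal
minutes/day with geometrically decaying means (45 × 0.78^k from bin 3), a
subject-level volume factor, and a heavy-tailed per-subject activity
ceiling (`12 + Exp(rate 0.28)` bins) that empties high bins for most
subjects — participation declines from ~100% through bin 12 to about 45% in
the lower very-vigorous bins and 6% in the last, the shape seen in adult
cohorts. The volume factor couples to the ceiling (`exp(0.045·(C−12))`):
subjects who ever reach vigorous intensities are overall more active, so
their sedentary remainder — wear minus active time, split ~75/25 over the
two sedentary bins — shrinks. That coupling is what makes sedentary time
trade off against planted high-intensity time, the way it does in real
cohorts. The latent health score is `h = √es·z(planted minutes) +
√(1−es)·z(noise)`, with the noise orthogonalized against the signal so the
in-sample effect size is *exact*, not approximate. Markers are noisy affine
transforms of −h (fitness of +h) on realistic clinical scales for a
middle-aged cohort, with per-marker correlation 0.72 to the latent score,
which makes the recomputed composite correlate ≈ 0.93 with it; insulin is
back-computed from a generated HOMA target and an independent glucose so
the planted signal flows through the HOMA formula.

**Paired-arm cohorts** (`simulate_cohort_paired()`): generated at the level
of minutes per locomotion speed (0–16 km/h), then mapped to each arm's mg
scale through the *actual designed filters*: output = (2A/π)·gain at the
speed's step frequency, with step frequency 1.2 + 0.14·speed Hz and
amplitude 0.0166·speed^1.71 g (calibrated so brisk walking lands near the
wide arm's moderate cut-point and fast running near the top of its range).
Fast running therefore maps to *decreasing* AG values but increasing wide
values — the two arms disagree exactly where the physics says they should.
A health effect planted on running minutes (≥ 8 km/h) then shows up at
light/moderate AG positions but vigorous wide positions, which is the
qualitative comparison the demo pipeline reproduces.

**Raw-signal days** (`simulate_raw_day()`): gravity on one axis plus a
single dominant sinusoid per activity segment plus 3 mg white noise;
non-wear segments are constant gravity exactly. A single sinusoid is enough
to exercise the filter-discrimination mechanism; gait harmonics, posture
changes, device calibration error and idle-sleep artifacts are *not*
modeled. Consequently, passing tests demonstrate that the pipeline's
mechanisms work as specified — they do not certify accuracy on real
free-living recordings, where impacts and harmonics spread energy across
bins.

All randomness flows from one master seed through `derive_seed(seed,
stream)`, a fixed Lehmer-style splitting scheme; identical seeds give
byte-identical cohorts.

## 8. Problem sizes and numerical conventions

The packaged checks use cohorts of n = 700 (recovery of an effect planted
in bins 15–18 at effect size 0.15; the peak |SR| falls inside the planted
range in ≥ 95% of 20 replicates), n = 500 (null calibration: median
held-out R² below 0.05), and n = 100 (two-arm demo through the full
pipeline). These sizes give stable statistics at interactive runtimes.

Conventions worth restating: intervals are half-open everywhere (an epoch
value equal to a bin edge or cut-point joins the upper bin/class; an epoch
starting exactly at 06:00 survives night removal); "zero" output means
≤ 10⁻⁶ mg; the non-wear allowance is cumulative and may touch window edges;
percentiles interpolate linearly (type 7); ties in component selection go
to fewer components; R integer seeds stay below 2³¹.

## 9. Known limitations

- The AG arm emulates a frequency band, not the full ActiGraph count chain;
  absolute mg values at high intensity are lower than a single-pass chain
  would give, and the packaged AG cut-points are used with the package's
  own zero-phase chain.
- The composite score treats the six markers as exchangeable after
  standardization; no measurement-error model, no covariate adjustment.
- Monte Carlo halves are unstratified; with two pooled cohorts,
  stratification could slightly narrow the intervals.
- The resampling CIs reuse the chosen-count draws from the same pass rather
  than refitting the selection per draw, so selection uncertainty is not
  propagated into the intervals.
- Synthetic gait is a single sinusoid; the generators emulate the
  *structure* of cohort spectra (collinearity, skew, zero inflation,
  participation decline), not any particular population's values.
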