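# accelspec

Relating the full physical-activity intensity spectrum, measured from raw
accelerometry, to cardiometabolic health.

## The problem

Epidemiological physical-activity research has mostly relied on ActiGraph
counts. The count chain applies a narrow frequency filter (low-pass corner
around 1.6 Hz) to the raw acceleration signal. Because running cadence rises
with speed, the narrow band progressively discards the very content that
distinguishes vigorous from moderate activity: the output plateaus at
running speeds and then *reverses*, so high-intensity activity is
misclassified. Widening the band to a 10 Hz low-pass corner keeps all
frequency content of human movement and restores a monotone dose-response
between epoch output and intensity.

`accelspec` implements both processing arms side by side and the statistics
needed to compare them against health outcomes:

1. **Signal processing** — raw 30 Hz tri-axial acceleration (±6 g) is
   band-pass filtered (0.29–1.6 Hz "AG" arm or 0.29–10 Hz "wide" arm,
   4th-order Butterworth, zero phase) and aggregated to 3-s epochs of mean
   vector-norm amplitude in mg.
2. **Wear validity** — night time (00:00–06:00) removed; non-wear detected
   as ≥ 60 min of zero epochs with a ≤ 2 min sub-threshold (< 19.1 mg)
   allowance, always on the AG arm, whose mask is the reference for both
   arms; valid day = ≥ 8 h wear; valid measurement = ≥ 4 valid days.
3. **Intensity spectrum** — minutes/day in 22 half-open bins (AG edges
   0, 10, 20, 40, … +20 mg; wide edges 0, 40, 80, 160, … +80 mg, final bin
   open), plus MET-anchored class minutes (SED/LPA/MPA/VPA/VVPA at
   19.1/63.0/171.0/300.2 mg for AG, 38.9/167.2/582.3/994.1 mg for wide).
4. **Cardiometabolic composite score** — six markers (systolic BP,
   triglycerides, total-cholesterol:HDL, HOMA = glucose·insulin/22.5,
   waist:height, fitness); all but fitness reversed, each z-standardized,
   composite = mean of the six, so higher = healthier.
5. **Association model** — partial least squares regression of the
   composite score on the spectrum, collapsed by target projection and
   summarized as signed selectivity ratios (see below).
6. **Synthetic cohorts** — generators with known ground truth (planted
   effect location and size) so that every stage, and the recovery of a
   planted effect through the whole pipeline, is testable without cohort
   data.

## The model

For standardized spectrum matrix **X** (n × p) and composite score **y**,
NIPALS PLS extracts components a = 1…A:

    w_a = X'y / ‖X'y‖,  t_a = X w_a,  p_a = X't_a / t_a't_a,
    q_a = y't_a / t_a't_a,  X ← X − t_a p_a'

with regression vector **b** = W(P'W)⁻¹q. A is chosen by Monte Carlo
cross-validation: 100 random half-splits, fit on one half, RMSE on the
other; the A with the lowest median RMSE wins. The model is then collapsed
onto its predictive direction (*target projection*):

    w_tp = b/‖b‖,  t_tp = X w_tp,  p_tp = X' t_tp / t_tp't_tp

and each bin j gets a *selectivity ratio*

    SR_j = ‖t_tp‖² p_tp,j² / (‖x_j‖² − ‖t_tp‖² p_tp,j²),  signed by p_tp,j

the ratio of variance in bin j explained by the predictive component to the
residual variance — a variance-independent association measure. The same
resampling draws give 95% percentile confidence intervals for the SRs and
for the explained variance R².

## Worked example

Simulate a 100-subject cohort through the physical filter mechanism (each
locomotion speed maps to an AG and a wide epoch value via the actual
designed filters), with a health effect planted on minutes of running at
8 km/h and above, and analyze both arms:

```r
library(accelspec)
co  <- simulate_cohort_paired(n_subjects = 100, effect_size = 0.15, seed = 1)
res <- run_pipeline(co, accel_config(reps = 100, seed = 1))
#> AG arm: 1 component(s), R2 = 2.6%, peak |SR| at bin 4 ([40,60))
#> WIDE arm: 1 component(s), R2 = 12.6%, peak |SR| at bin 13 ([880,960))
print(res)
#> Pipeline result
#>   subjects analyzed: 100 (excluded: 0)
#>   AG  : 1 comp, R2 2.6% (CI 1.5-24.7%), peak |SR| bin 4, MET position 1.48
#>   WIDE: 1 comp, R2 12.6% (CI 11.4-35.8%), peak |SR| bin 13, MET position 3.72
```

Both arms see the same physical behaviour, but the narrow AG arm compresses
running into its light/moderate range (peak association at MET-scale
position 1.48, i.e. within LPA), while the wide arm resolves it where it
belongs (position 3.72, upper VPA) and explains substantially more of the
composite-score variance. `plot(res$wide$fit)` draws the selectivity-ratio
bar plot with confidence whiskers and intensity-class annotations.

```r
fit <- res$wide$fit
head(summary(fit)$table, 4)
#>         bin           sr      ci_low   ci_high   coefficient
#> 1    [0,40) -0.131623540 -0.51722704 0.1441462 -0.0492114976
#> 2   [40,80)  0.006089886 -0.08354959 0.1139707  0.0009924264
#> 3  [80,160) -0.011273323 -0.25649342 0.1359335 -0.0401503065
#> 4 [160,240)  0.281734446 -0.02521414 0.8868425  0.0737487967
```

Sedentary time (bin 1) carries a negative sign — more sitting, worse
composite score — and the planted high-intensity range carries the peak.

## Package layout

- `R/filters.R` — filter design, zero-phase filtering, epoch aggregation, CSV I/O
- `R/wear.R` — night removal, non-wear detection, day/measurement validity
- `R/spectrum.R` — bin schemes, time-in-bins, MET classes, participation
- `R/cardiometabolic.R` — HOMA and the composite score
- `R/pls.R`, `R/mccv.R`, `R/sr-pls.R` — the association model and its methods
- `R/synthetic.R` — raw-signal and cohort generators with ground truth
- `R/pipeline.R` — orchestration, configuration, descriptives
- `vignettes/intensity-spectrum-pls.Rmd` — the methods vignette
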