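# rhythmkit

Quantification of circadian rhythms in bioluminescence recordings,
single-cell time-lapse imaging, wheel-running behaviour and expression
data — the analysis chain of a suprachiasmatic nucleus (SCN) pharmacology
study, implemented as a tested, tidyverse-style R package.

Circadian experiments on SCN slices and mice generate four kinds of data,
each with its own quantification conventions:

* **Ensemble bioluminescence traces** (e.g. PER2::LUC photon counts in 6-min
  bins): period, amplitude, damping and the relative amplitude error (RAE)
  from an FFT-seeded nonlinear least-squares fit of a damped cosine
  `y(t) = c0 + c1 t + A e^(−λt) cos(2π(t−φ)/T)`; treatment responses as the
  phase shift by peak extrapolation (delays negative), acute fold induction
  by exponential ("growth") extrapolation of the three preceding peaks,
  period and amplitude change between pre/post fits, and an RMS change
  metric for arrhythmic (clock-deficient) recordings.
* **Time-lapse image stacks**: ROI detection by thresholding the temporal
  SD projection, per-cell traces feeding the same rhythm fits, Rayleigh
  phase-coherence statistics (mean resultant length `R = |mean e^{iθ}|`),
  and centre-of-mass (CoM) descriptors of the spatiotemporal wave — the
  mean cycle path, its perimeter and principal direction.
* **Wheel-running actograms**: the Sokolove–Bushell chi-squared periodogram
  with a multiplicity-corrected significance line, activity onset/offset
  detection, phase angle of entrainment, activity duration (alpha),
  re-entrainment PS50 from a 4-parameter logistic, and Aschoff Type II
  light-pulse shifts by onset-regression extrapolation.
* **Expression matrices**: detection-p filtering, log2 + quantile
  normalisation, a moments-based moderated t with Benjamini–Hochberg FDR,
  and promoter CRE-category enrichment by chi-square against background
  ratios.

Each module is paired with a seeded synthetic generator
(`simulate_ensemble()`, `simulate_wave_field()`, `simulate_actogram()`,
`simulate_expression()`) that plants known ground truth, so every estimator
is validated by parameter recovery. Results are tibbles or small S3 objects
with `tidy()`/`glance()` methods and `autoplot()` graphics.

## Worked example

Simulate a ten-day slice recording treated at CT10 of the fifth cycle with
a planted 4 h phase delay and 1.5-fold acute induction, then run the full
response analysis:

```r
library(rhythmkit)

tr <- simulate_ensemble(treatment_time_h = 106, d_phase_h = -4,
                        induction_fold = 1.5, noise_sd = 5, seed = 11)
treatment_response(tr)[, 1:5]
#> # A tibble: 1 × 5
#>   phase_shift_h fold_induction d_period_h amplitude_change_pct rms_change_pct
#>           <dbl>          <dbl>      <dbl>                <dbl>          <dbl>
#> 1         -3.81           1.42    -0.0135                -16.9          -38.5
```

The planted 4 h delay is recovered as `phase_shift_h = -3.81` (negative =
delay), and the acute induction as `fold_induction = 1.42` — slightly under
the planted 1.5 because the induction transient decays over the two hours
between treatment at CT10 and the next peak, exactly as it would in a real
recording. The pre-treatment damped-cosine fit itself:

```r
glance(treatment_response(tr)$pre_fit[[1]])[, c(1, 2, 5)]
#> # A tibble: 1 × 3
#>   period_h amplitude    rae
#> 1     24.0      93.8 0.0119
```

a 24.0 h rhythm of amplitude ~94 cps with RAE 0.012 (0 = perfectly robust
rhythm, 1 = no rhythm). Phase coherence across cells works the same way:

```r
glance(rayleigh_test(c(11.8, 12.4, 12.1, 13.0, 11.5, 12.6)))[, c("R", "mean_phase_h", "n", "p_value")]
#> # A tibble: 1 × 4
#>       R mean_phase_h     n   p_value
#> 1 0.991         12.2     6 0.0000485
```

six cells peaking near CT12 with near-perfect synchrony (`R = 0.99`).

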