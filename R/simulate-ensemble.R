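# Synthetic ensemble bioluminescence traces with known ground truth.

# Run code with a local RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic ensemble bioluminescence trace
#'
#' Describes a damped ~24 h oscillation of the kind recorded from organotypic
#' SCN slices on photomultiplier tubes, with an optional treatment applied
#' mid-recording that can delay phase, lengthen period, scale amplitude and
#' acutely induce the reporter. The model is phenomenological:
#'
#' `y(t) = baseline + drift * t + A * exp(-lambda * t) * cos(2 pi (t - phase) / T) + noise`
#'
#' After `treatment_time_h` the oscillatory term switches to period
#' `T + d_period_h`, its peaks are displaced by `-d_phase_h` relative to the
#' extrapolated pre-treatment peaks (so `d_phase_h = -4` plants a 4 h delay),
#' and its amplitude is scaled by `amp_scale`. An additive induction transient
#' of initial height `(induction_fold - 1)` times the extrapolated next peak
#' value rises instantaneously at treatment and decays exponentially with time
#' constant `induction_decay_h`. Damping applies to the oscillation only, not
#' the baseline, matching decaying peak envelopes over stable troughs.
#'
#' @param duration_h Recording length (hours). Must cover at least 3 periods.
#' @param dt_h Sampling interval in hours; 0.1 h reproduces 6-min binning of
#'   photon counts.
#' @param period_h,phase_h,amplitude Free-running period (h), time of first
#'   peak (h) and initial oscillation amplitude (cps).
#' @param damping_rate Exponential damping of the oscillatory term (per hour).
#' @param baseline,baseline_drift Constant baseline (cps) and linear drift
#'   (cps/h).
#' @param noise_sd Gaussian measurement noise SD (cps).
#' @param treatment_time_h Time of treatment (h), or `NULL` for an untreated
#'   recording.
#' @param d_phase_h Planted phase shift (h); negative values are delays.
#' @param d_period_h Planted period change (h).
#' @param amp_scale Post-treatment amplitude scaling in \[0, 1\].
#' @param induction_fold Planted acute induction: ratio of the first
#'   post-treatment peak to the extrapolated peak (>= 0; 1 = no induction).
#' @param induction_decay_h Decay time constant of the induction transient (h).
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return A validated list of class `ensemble_spec`.
#' @seealso [simulate_ensemble()]
#' @export
ensemble_spec <- function(duration_h = 240, dt_h = 0.1, period_h = 24,
                          phase_h = 12, amplitude = 100, damping_rate = 0.006,
                          baseline = 200, baseline_drift = 0, noise_sd = 0,
                          treatment_time_h = NULL, d_phase_h = 0,
                          d_period_h = 0, amp_scale = 1, induction_fold = 1,
                          induction_decay_h = 24, seed = 1L) {
  spec <- list(duration_h = duration_h, dt_h = dt_h, period_h = period_h,
               phase_h = phase_h, amplitude = amplitude,
               damping_rate = damping_rate, baseline = baseline,
               baseline_drift = baseline_drift, noise_sd = noise_sd,
               treatment_time_h = treatment_time_h, d_phase_h = d_phase_h,
               d_period_h = d_period_h, amp_scale = amp_scale,
               induction_fold = induction_fold,
               induction_decay_h = induction_decay_h, seed = as.integer(seed))
  check_that(is.numeric(dt_h) && dt_h > 0, "dt_h", "must be > 0")
  check_that(is.numeric(period_h) && period_h > 0, "period_h", "must be > 0")
  check_that(duration_h >= 3 * period_h, "duration_h",
             "must span at least 3 periods")
  check_that(amp_scale >= 0 && amp_scale <= 1, "amp_scale",
             "must lie in [0, 1]")
  check_that(induction_fold >= 0, "induction_fold", "must be >= 0")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(induction_decay_h > 0, "induction_decay_h", "must be > 0")
  if (!is.null(treatment_time_h)) {
    check_that(treatment_time_h > 0 && treatment_time_h < duration_h,
               "treatment_time_h", "must fall inside the recording")
  }
  structure(spec, class = "ensemble_spec")
}

# Noiseless signal as a vectorised function of time. Exposed internally so the
# ground truth can be refined on a continuous axis.
ensemble_signal <- function(spec, t) {
  s <- spec
  base <- s$baseline + s$baseline_drift * t
  env <- s$amplitude * exp(-s$damping_rate * t)
  pre <- env * cos(2 * pi * (t - s$phase_h) / s$period_h)
  t0 <- s$treatment_time_h
  if (is.null(t0)) return(base + pre)

  # first extrapolated cosine-grid peak strictly after treatment
  k_next <- floor((t0 - s$phase_h) / s$period_h) + 1
  p_next <- s$phase_h + k_next * s$period_h
  period_post <- s$period_h + s$d_period_h
  anchor <- p_next - s$d_phase_h
  post <- s$amp_scale * env * cos(2 * pi * (t - anchor) / period_post)

  pred_peak_value <- s$baseline + s$baseline_drift * p_next +
    s$amplitude * exp(-s$damping_rate * p_next)
  h0 <- (s$induction_fold - 1) * pred_peak_value
  transient <- h0 * exp(-(t - t0) / s$induction_decay_h)

  after <- t >= t0
  base + ifelse(after, post + transient, pre)
}

# Numerically refined peak times of the noiseless signal.
ensemble_truth_peaks <- function(spec) {
  s <- spec
  t0 <- s$treatment_time_h
  f <- function(t) ensemble_signal(s, t)
  guesses <- s$phase_h + s$period_h * (0:floor((s$duration_h - s$phase_h) / s$period_h))
  if (!is.null(t0)) {
    period_post <- s$period_h + s$d_period_h
    k_next <- floor((t0 - s$phase_h) / s$period_h) + 1
    anchor <- s$phase_h + k_next * s$period_h - s$d_phase_h
    guesses <- guesses[guesses < t0]
    if (s$amp_scale > 0) {
      post <- anchor + period_post * (0:floor((s$duration_h - anchor) / period_post))
      guesses <- c(guesses, post[post >= t0 & post <= s$duration_h])
    }
  }
  guesses <- guesses[guesses >= 0 & guesses <= s$duration_h]
  peaks <- vapply(guesses, function(g) {
    lo <- max(0, g - s$period_h / 4)
    hi <- min(s$duration_h, g + s$period_h / 4)
    optimize(f, c(lo, hi), maximum = TRUE)$maximum
  }, numeric(1))
  tibble(peak_time_h = peaks, peak_value = f(peaks))
}

#' Simulate an ensemble bioluminescence trace
#'
#' Generates the deterministic signal described by [ensemble_spec()] plus
#' Gaussian noise, and attaches the ground truth (noiseless peak times and
#' values, extrapolated next-peak prediction, treatment circadian time) for
#' parameter-recovery testing. With circadian time defined so that CT12 is the
#' reporter peak, the treatment CT reported is
#' `(12 + (t0 - previous peak) * 24 / period) mod 24`.
#'
#' @param spec An [ensemble_spec()], or arguments passed on to it via `...`.
#' @param ... Passed to [ensemble_spec()] when `spec` is missing.
#'
#' @return An [as_trace()] tibble (`time_h`, `value`, `treated`) whose
#'   [sim_truth()] holds `spec`, `peaks`, `predicted_peak` and `ct_treatment`.
#' @export
#'
#' @examples
#' tr <- simulate_ensemble(duration_h = 120, noise_sd = 0)
#' head(sim_truth(tr)$peaks)
simulate_ensemble <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- ensemble_spec(...)
  check_that(inherits(spec, "ensemble_spec"), "spec",
             "must be an `ensemble_spec`")
  t <- seq(0, spec$duration_h, by = spec$dt_h)
  y <- ensemble_signal(spec, t)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(spec$seed, rnorm(length(t), 0, spec$noise_sd))
  }
  t0 <- spec$treatment_time_h
  out <- tibble(time_h = t, value = y,
                treated = if (is.null(t0)) FALSE else t >= t0)
  out <- as_trace(out, treatment_time_h = t0)

  peaks <- ensemble_truth_peaks(spec)
  truth <- list(spec = spec, peaks = peaks)
  if (!is.null(t0)) {
    k_next <- floor((t0 - spec$phase_h) / spec$period_h) + 1
    p_next <- spec$phase_h + k_next * spec$period_h
    p_prev <- p_next - spec$period_h
    truth$predicted_peak <- list(
      time_h = p_next,
      value = spec$baseline + spec$baseline_drift * p_next +
        spec$amplitude * exp(-spec$damping_rate * p_next))
    truth$ct_treatment <- (12 + (t0 - p_prev) * 24 / spec$period_h) %% 24
  }
  attr(out, "truth") <- truth
  out
}
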