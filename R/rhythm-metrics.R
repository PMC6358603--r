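# Treatment-response metrics computed from ensemble traces: phase shift by
# peak extrapolation, acute fold induction by growth extrapolation, RMS change
# for arrhythmic recordings, and amplitude/period changes between fits.

#' Phase shift by peak extrapolation
#'
#' Predicts where bioluminescence peaks would have occurred without treatment
#' by extrapolating multiples of the pre-treatment period from the last
#' pre-treatment peak, and compares them with the observed post-treatment
#' peaks. The shift is the mean of (predicted - observed) over the analysis
#' window, so delays (peaks later than predicted) are negative and advances
#' positive. Each observed peak is paired with its nearest predicted peak,
#' which caps the usable shift at half a period and avoids cycle-skipping.
#'
#' The default windows follow standard practice for slice recordings: four
#' days of data before treatment, and four days after excluding the first
#' 36 h while the rhythm settles.
#'
#' @inheritParams detrend_rolling
#' @param treatment_time_h Treatment time (h); defaults to the trace
#'   attribute.
#' @param pre_window_h,post_window_h Analysis window lengths (h).
#' @param exclude_post_h Post-treatment hours excluded from the comparison.
#' @param peak_refine_h Quadratic refinement half-width passed to
#'   [detect_peaks()]; wider than the general default because any
#'   waveform-shape bias it introduces is common to the observed and
#'   predicted peaks and cancels in the shift, while the noise suppression
#'   does not.
#'
#' @return A one-row tibble with `phase_shift_h` (negative = delay),
#'   `pre_period_h` and `n_peaks_used`.
#' @export
#'
#' @examples
#' tr <- simulate_ensemble(treatment_time_h = 106, d_phase_h = -4)
#' phase_shift(tr)
phase_shift <- function(trace, treatment_time_h = NULL, pre_window_h = 96,
                        post_window_h = 96, exclude_post_h = 36,
                        peak_refine_h = 6) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  t0 <- resolve_t0(trace, treatment_time_h)

  # peaks are detected on each side of the treatment separately: the abrupt
  # waveform change at treatment otherwise leaves a truncation artifact that
  # can be mistaken for the last pre-treatment peak
  pre_seg <- trace[trace$time_h <= t0, ]
  post_seg <- trace[trace$time_h >= t0, ]
  pre <- detect_peaks(as_trace(pre_seg), refine_h = peak_refine_h)
  pre <- pre[pre$peak_time_h >= t0 - pre_window_h, ]
  if (nrow(pre) < 3) {
    abort("fewer than 3 pre-treatment peaks in the analysis window")
  }
  post <- detect_peaks(as_trace(post_seg), refine_h = peak_refine_h)
  post <- post[post$peak_time_h >= t0 + exclude_post_h &
                 post$peak_time_h <= t0 + post_window_h, ]
  if (nrow(post) < 2) {
    abort("fewer than 2 post-treatment peaks in the analysis window")
  }

  pre_fit <- fit_fftnlls(trace, window = c(t0 - pre_window_h, t0))
  period <- if (pre_fit$arrhythmic) {
    mean(diff(pre$peak_time_h))
  } else {
    pre_fit$period_h
  }

  p_last <- max(pre$peak_time_h)
  k <- seq_len(ceiling((max(post$peak_time_h) - p_last) / period) + 1)
  predicted <- p_last + k * period
  d <- vapply(post$peak_time_h, function(obs) {
    obs - predicted[which.min(abs(obs - predicted))]
  }, numeric(1))
  d <- d[abs(d) <= period / 2]

  tibble(phase_shift_h = -mean(d), pre_period_h = period,
         n_peaks_used = length(d))
}

#' Exponential ("growth") extrapolation of peak values
#'
#' Log-linear least squares through a short series of peak values, evaluated
#' one step ahead - the spreadsheet growth-function extrapolation used to
#' predict the next undisturbed bioluminescence peak.
#'
#' @param values Positive peak values, in temporal order.
#' @param n_ahead Steps beyond the last value at which to evaluate.
#' @return The extrapolated value.
#' @export
#'
#' @examples
#' growth_extrapolate(c(100, 90, 81)) # 72.9
growth_extrapolate <- function(values, n_ahead = 1) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("peak values must be positive for growth extrapolation")
  }
  i <- seq_along(values)
  fit <- lm(log(values) ~ i)
  unname(exp(predict(fit, data.frame(i = length(values) + n_ahead))))
}

#' Acute fold induction of the reporter
#'
#' Ratio of the first observed post-treatment peak to the peak predicted by
#' exponential extrapolation of the three pre-treatment peaks. A fold of 1
#' means the treatment merely continued the damping trend; values above 1
#' quantify acute induction.
#'
#' @inheritParams phase_shift
#' @param n_pre_peaks Number of pre-treatment peaks entering the
#'   extrapolation (3 by convention).
#'
#' @return A one-row tibble with `fold_induction`, `predicted_peak_value` and
#'   `observed_peak_value`.
#' @export
fold_induction <- function(trace, treatment_time_h = NULL, n_pre_peaks = 3) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  t0 <- resolve_t0(trace, treatment_time_h)
  # pre/post segments are analysed separately so the waveform break at
  # treatment cannot masquerade as a peak; the induced peak may sit right
  # after treatment, so the post segment keeps its leading edge
  pre <- detect_peaks(as_trace(trace[trace$time_h <= t0, ]))
  if (nrow(pre) < n_pre_peaks) {
    abort(sprintf("fewer than %d pre-treatment peaks", n_pre_peaks))
  }
  pre <- utils::tail(pre, n_pre_peaks)
  post <- detect_peaks(as_trace(trace[trace$time_h >= t0, ]),
                       edge_exclude_h = 0)
  post <- post[post$peak_time_h > t0, ]
  if (nrow(post) < 1) {
    abort("no post-treatment peak found")
  }
  predicted <- growth_extrapolate(pre$peak_value)
  observed <- post$peak_value[1]
  tibble(fold_induction = observed / predicted,
         predicted_peak_value = predicted, observed_peak_value = observed)
}

#' Acute induction for arrhythmic recordings
#'
#' For recordings without a usable oscillation (e.g. Cry-null slices) the
#' induction is measured directly: the trace is normalised to its own
#' maximum, and the statistic is the highest normalised value within the
#' `window_h` hours after treatment minus the normalised value immediately
#' before treatment.
#'
#' @inheritParams phase_shift
#' @param window_h Post-treatment window searched for the maximum (h).
#' @return A one-row tibble with `acute_induction` (normalised units).
#' @export
acute_induction <- function(trace, treatment_time_h = NULL, window_h = 6) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  t0 <- resolve_t0(trace, treatment_time_h)
  if (max(trace$time_h) < t0 + window_h) {
    abort(sprintf("need at least %g h of post-treatment data", window_h))
  }
  ynorm <- trace$value / max(trace$value)
  before <- ynorm[max(which(trace$time_h < t0))]
  in_win <- trace$time_h > t0 & trace$time_h <= t0 + window_h
  tibble(acute_induction = max(ynorm[in_win]) - before)
}

#' RMS change of the detrended signal
#'
#' An amplitude analogue for arrhythmic recordings: the trace is normalised
#' to its maximum, a 24 h rolling baseline is subtracted, and the root mean
#' square of the residual is compared between a pre-treatment window and a
#' post-treatment window separated from treatment by a gap (defaults: 48 h
#' before treatment vs. 48 h starting 24 h after treatment).
#'
#' @inheritParams phase_shift
#' @param pre_window_h,post_window_h,gap_h Window lengths and post-treatment
#'   gap, in hours.
#' @param detrend_window_h Rolling-baseline width (h).
#' @return A one-row tibble with `rms_change_pct` (100 * (post - pre) / pre),
#'   `rms_pre` and `rms_post`.
#' @export
rms_change <- function(trace, treatment_time_h = NULL, pre_window_h = 48,
                       post_window_h = 48, gap_h = 24,
                       detrend_window_h = 24) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  t0 <- resolve_t0(trace, treatment_time_h)
  if (t0 - pre_window_h < min(trace$time_h) ||
      t0 + gap_h + post_window_h > max(trace$time_h)) {
    abort("trace does not cover the pre/post RMS windows")
  }
  norm <- trace
  norm$value <- trace$value / max(trace$value)
  det <- detrend_rolling(norm, detrend_window_h)
  t <- det$time_h
  rms <- function(sel) sqrt(mean(det$value[sel]^2))
  rms_pre <- rms(t >= t0 - pre_window_h & t < t0)
  rms_post <- rms(t >= t0 + gap_h & t < t0 + gap_h + post_window_h)
  tibble(rms_change_pct = 100 * (rms_post - rms_pre) / rms_pre,
         rms_pre = rms_pre, rms_post = rms_post)
}

#' Amplitude and period change between two rhythm fits
#'
#' Percentage amplitude change and absolute period change from a
#' pre-treatment to a post-treatment [fit_fftnlls()] fit. Because fitted
#' amplitudes are referenced to each window's start while the oscillation
#' damps, both amplitudes are extrapolated along their fitted envelopes to a
#' common reference time (`at_time_h`, by default the end of the pre window,
#' i.e. the treatment time) before the ratio is taken; without this the
#' intrinsic damping between the two windows would masquerade as a treatment
#' effect.
#'
#' @param pre_fit,post_fit `rhythm_fit` objects for the pre- and
#'   post-treatment windows.
#' @param at_time_h Reference time for the amplitude comparison (h).
#' @return A one-row tibble with `amplitude_change_pct` and
#'   `period_change_h`.
#' @export
amplitude_change <- function(pre_fit, post_fit,
                             at_time_h = pre_fit$window[2]) {
  if (pre_fit$arrhythmic || post_fit$arrhythmic) {
    abort("amplitude change requires two rhythmic fits")
  }
  amp_at <- function(fit) {
    fit$amplitude * exp(-fit$damping_rate * (at_time_h - fit$window[1]))
  }
  tibble(
    amplitude_change_pct = 100 * (amp_at(post_fit) - amp_at(pre_fit)) / amp_at(pre_fit),
    period_change_h = post_fit$period_h - pre_fit$period_h)
}

#' Correlate two per-slice response measures
#'
#' Pearson correlation with a two-sided t test, plus the ordinary
#' least-squares line, for paired response measures such as phase shift
#' versus acute fold induction.
#'
#' @param data A data frame of paired responses.
#' @param x,y Columns to correlate (tidy evaluation).
#' @return A one-row tibble with `pearson_r`, `p_value`, `slope`,
#'   `intercept` and `n`.
#' @export
#'
#' @examples
#' df <- data.frame(induction = 1:6 / 2, shift = -(1:6) / 1.5)
#' correlate_responses(df, induction, shift)
correlate_responses <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation is undefined for a constant variable")
  }
  ct <- cor.test(xv, yv)
  fit <- lm(yv ~ xv)
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = length(xv))
}

#' Full treatment response of one trace
#'
#' Convenience wrapper running the whole per-slice response analysis: fits
#' the pre- and post-treatment windows, and computes phase shift, fold
#' induction, period change and amplitude change (plus RMS change when the
#' recording covers the RMS windows).
#'
#' @inheritParams phase_shift
#' @return A one-row tibble with the response metrics and the two fits as
#'   list columns `pre_fit` and `post_fit`.
#' @export
treatment_response <- function(trace, treatment_time_h = NULL,
                               pre_window_h = 96, post_window_h = 96,
                               exclude_post_h = 36) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  t0 <- resolve_t0(trace, treatment_time_h)
  pre_fit <- fit_fftnlls(trace, window = c(t0 - pre_window_h, t0))
  post_fit <- fit_fftnlls(
    trace, window = c(t0 + exclude_post_h,
                      min(max(trace$time_h), t0 + exclude_post_h + post_window_h)))
  ps <- phase_shift(trace, t0, pre_window_h, post_window_h, exclude_post_h)
  fi <- fold_induction(trace, t0)
  ac <- if (!pre_fit$arrhythmic && !post_fit$arrhythmic) {
    amplitude_change(pre_fit, post_fit, at_time_h = t0)
  } else {
    tibble(amplitude_change_pct = NA_real_, period_change_h = NA_real_)
  }
  rc <- tryCatch(rms_change(trace, t0)$rms_change_pct,
                 error = function(e) NA_real_)
  tibble(phase_shift_h = ps$phase_shift_h,
         fold_induction = fi$fold_induction,
         d_period_h = ac$period_change_h,
         amplitude_change_pct = ac$amplitude_change_pct,
         rms_change_pct = rc,
         pre_fit = list(pre_fit), post_fit = list(post_fit))
}
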