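# Shared builders for the test suite. Fixtures are always generated in code.

# A plain cosine trace with optional drift/noise, built without the package's
# own generator so generator and estimator tests stay independent.
cosine_trace <- function(duration_h = 120, dt_h = 0.1, period_h = 24,
                         phase_h = 12, amplitude = 100, baseline = 0,
                         drift = 0, noise_sd = 0, seed = NULL) {
  t <- seq(0, duration_h, by = dt_h)
  y <- baseline + drift * t +
    amplitude * cos(2 * pi * (t - phase_h) / period_h)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  as_trace(data.frame(time_h = t, value = y))
}

# Brute-force centred moving average (independent oracle for detrending).
brute_moving_average <- function(y, width) {
  n <- length(y)
  half <- (width - 1) / 2
  sapply(seq_len(n), function(i) {
    lo <- max(1, ceiling(i - half))
    hi <- min(n, floor(i + half))
    mean(y[lo:hi])
  })
}

# Dense grid-search least-squares oracle for the period of an undamped
# cosine plus linear trend (independent of the FFT-NLLS path).
grid_search_period <- function(trace, band = c(16, 32), step = 0.01) {
  t <- trace$time_h
  y <- trace$value
  periods <- seq(band[1], band[2], by = step)
  rss <- vapply(periods, function(Tp) {
    w <- 2 * pi / Tp
    X <- cbind(1, t, cos(w * t), sin(w * t))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  periods[which.min(rss)]
}

# Jet-lag schedule: `pre_days` entrained days, then the lighting cycle
# delayed/advanced by `shift_h` for `post_days`.
jetlag_schedule <- function(shift_h, pre_days = 6, post_days = 14,
                            lights_on_h = 6, lights_off_h = 18) {
  list(list(mode = "LD", days = pre_days, lights_on_h = lights_on_h,
            lights_off_h = lights_off_h),
       list(mode = "LD", days = post_days, lights_on_h = lights_on_h + shift_h,
            lights_off_h = lights_off_h + shift_h))
}

# Aschoff Type II schedule: entrained days, one pulse day, then darkness.
aschoff2_schedule <- function(ld_days = 7, dd_days = 10) {
  list(list(mode = "LD", days = ld_days, lights_on_h = 6, lights_off_h = 18),
       list(mode = "light_pulse", days = 1),
       list(mode = "DD", days = dd_days))
}

# PS50 markers from a jet-lag record: onsets indexed by days since the shift
# (cycle-based so onsets drifting past midnight keep their day index).
ps50_markers <- function(record, shift_cycle) {
  oo <- detect_onsets_offsets(record)
  sel <- oo$cycle > shift_cycle
  data.frame(day = oo$cycle[sel] - shift_cycle,
             marker_h = oo$onset_clock_h[sel])
}
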