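# Synthetic wheel-running actograms: entrained, free-running, jet-lagged and
# light-pulsed schedules with known onset ground truth.

#' Specification of a synthetic actogram
#'
#' Activity is modelled as Poisson counts per bin: `bout_rate` inside the
#' daily activity window (onset to onset + `alpha_h`), 2% of `bout_rate`
#' outside, so onset detectors face a realistic nonzero background. Onsets
#' follow the light schedule:
#'
#' * `LD` segments: the steady-state onset sits `phase_angle_min` minutes
#'   before lights-off (positive angle = onset before lights-off). After a
#'   schedule shift the onset approaches the new steady state along a
#'   logistic in days with midpoint `reentrain_ps50_day` and slope
#'   `reentrain_slope` (re-entrainment during jet lag).
#' * `DD` segments: onsets drift by `tau_dd_h - 24` per day (free run).
#' * `light_pulse` segments: one DD-style day whose pulse shifts all
#'   subsequent onsets by `pulse_shift_h` (negative = delay, i.e. later
#'   onsets), the Aschoff Type II protocol.
#'
#' @param n_days Ignored when `schedule` is given; otherwise length of the
#'   default single LD block.
#' @param bin_min Bin width in minutes (must divide 24 h evenly; default 6).
#' @param schedule List of segments, each a list with `mode`
#'   (`"LD"`, `"DD"` or `"light_pulse"`), `days`, and for LD segments
#'   `lights_on_h`/`lights_off_h` (clock hours).
#' @param tau_dd_h Free-running period in DD (h).
#' @param phase_angle_min Entrained phase angle (min; positive = onset
#'   before lights-off).
#' @param alpha_h Daily activity duration (h, < 24).
#' @param bout_rate Mean wheel revolutions per bin during activity.
#' @param reentrain_ps50_day,reentrain_slope Logistic re-entrainment
#'   midpoint (days after a shift) and slope (per day).
#' @param pulse_shift_h Phase shift caused by a light pulse (h; delays
#'   negative).
#' @param seed Integer seed.
#'
#' @return A validated list of class `actogram_spec`.
#' @export
actogram_spec <- function(n_days = 14, bin_min = 6, schedule = NULL,
                          tau_dd_h = 23.8, phase_angle_min = 0,
                          alpha_h = 10, bout_rate = 30,
                          reentrain_ps50_day = 4, reentrain_slope = 1,
                          pulse_shift_h = 0, seed = 1L) {
  check_that((24 * 60) %% bin_min == 0, "bin_min", "must divide 24 h evenly")
  check_that(alpha_h > 0 && alpha_h < 24, "alpha_h", "must lie in (0, 24)")
  check_that(bout_rate > 0, "bout_rate", "must be > 0")
  check_that(tau_dd_h > 0, "tau_dd_h", "must be > 0")
  if (is.null(schedule)) {
    schedule <- list(list(mode = "LD", days = n_days, lights_on_h = 6,
                          lights_off_h = 18))
  }
  for (seg in schedule) {
    check_that(seg$mode %in% c("LD", "DD", "light_pulse"), "schedule",
               "segment mode must be LD, DD or light_pulse")
    check_that(seg$days >= 1, "schedule", "segment must last >= 1 day")
  }
  structure(list(bin_min = bin_min, schedule = schedule, tau_dd_h = tau_dd_h,
                 phase_angle_min = phase_angle_min, alpha_h = alpha_h,
                 bout_rate = bout_rate,
                 reentrain_ps50_day = reentrain_ps50_day,
                 reentrain_slope = reentrain_slope,
                 pulse_shift_h = pulse_shift_h, seed = as.integer(seed)),
            class = "actogram_spec")
}

#' Simulate a wheel-running activity record
#'
#' Expands the schedule of an [actogram_spec()] day by day, tracks the
#' ground-truth activity onset (clock time, unwrapped across midnight), and
#' draws Poisson counts per bin. The result carries the per-day schedule and
#' the planted onsets for parameter-recovery testing.
#'
#' @param spec An [actogram_spec()], or arguments forwarded to it.
#' @param ... Passed to [actogram_spec()] when `spec` is missing.
#'
#' @return A tibble of class `rk_activity` with columns `bin`, `time_h`
#'   (bin start, hours from the record start at midnight), `day` and
#'   `counts`; attributes `bin_h`, `schedule` (per-day tibble) and `truth`
#'   (planted onsets/offsets and the spec).
#' @export
#'
#' @examples
#' rec <- simulate_actogram(n_days = 8)
#' head(sim_truth(rec)$onsets)
simulate_actogram <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- actogram_spec(...)
  check_that(inherits(spec, "actogram_spec"), "spec",
             "must be an `actogram_spec`")
  s <- spec

  # expand schedule into one row per day
  days <- purrr::map_dfr(seq_along(s$schedule), function(i) {
    seg <- s$schedule[[i]]
    tibble(segment = i, mode = seg$mode, day_in_seg = seq_len(seg$days),
           lights_on_h = seg$lights_on_h %||% NA_real_,
           lights_off_h = seg$lights_off_h %||% NA_real_)
  })
  days$day <- seq_len(nrow(days)) - 1L
  n_days <- nrow(days)

  # ground-truth onsets, unwrapped clock hours
  pa_h <- s$phase_angle_min / 60
  onset <- numeric(n_days)
  prev_steady <- NA_real_  # steady-state onset of the previous LD day
  shift_from <- NA_real_   # onset level a running logistic departs from
  shift_day <- NA_integer_
  shift_target <- NA_real_
  pulse_pending <- 0
  for (i in seq_len(n_days)) {
    mode <- days$mode[i]
    if (mode == "LD") {
      steady <- days$lights_off_h[i] - pa_h
      if (i == 1 || days$mode[i - 1] != "LD") {
        # entering LD afresh: assume already entrained
        onset[i] <- steady
      } else {
        if (!is.na(prev_steady) && abs(steady - prev_steady) > 1e-9) {
          # schedule shift: start a logistic approach to the new steady state
          shift_day <- days$day[i]
          shift_from <- onset[i - 1]
          shift_target <- steady
        }
        if (!is.na(shift_day)) {
          ds <- days$day[i] - shift_day + 1
          f <- 1 / (1 + exp(-s$reentrain_slope * (ds - s$reentrain_ps50_day)))
          onset[i] <- shift_from + (shift_target - shift_from) * f
          if (abs(onset[i] - shift_target) < 0.02) shift_day <- NA_integer_
        } else {
          onset[i] <- steady
        }
      }
      prev_steady <- steady
    } else if (mode == "light_pulse") {
      # the pulse falls in the early night, after that day's onset: the
      # animal is still entrained (or on its previous phase) on the pulse
      # day itself, and the shift appears from the next cycle
      onset[i] <- if (i == 1) 18 - pa_h else onset[i - 1]
      # shift expressed on the clock: a delay (negative) moves onsets later
      pulse_pending <- -s$pulse_shift_h
      prev_steady <- NA_real_
      shift_day <- NA_integer_
    } else {
      # DD day: free-running drift from the previous onset
      prev <- if (i == 1) 18 - pa_h else onset[i - 1]
      onset[i] <- prev + (s$tau_dd_h - 24) + pulse_pending
      pulse_pending <- 0
      prev_steady <- NA_real_
      shift_day <- NA_integer_
    }
  }

  bin_h <- s$bin_min / 60
  n_bins <- round(n_days * 24 / bin_h)
  tb <- (seq_len(n_bins) - 1) * bin_h
  rate <- rep(0.02 * s$bout_rate, n_bins)
  onset_abs <- days$day * 24 + onset
  for (i in seq_len(n_days)) {
    act <- tb >= onset_abs[i] & tb < onset_abs[i] + s$alpha_h
    rate[act] <- s$bout_rate
  }
  counts <- with_seed(s$seed, rpois(n_bins, rate))

  out <- tibble(bin = seq_len(n_bins), time_h = tb,
                day = floor(tb / 24), counts = counts)
  attr(out, "bin_h") <- bin_h
  attr(out, "schedule") <- as_tibble(days[, c("day", "segment", "mode",
                                              "lights_on_h", "lights_off_h")])
  attr(out, "truth") <- list(
    spec = s,
    onsets = tibble(day = days$day, onset_clock_h = onset,
                    onset_abs_h = onset_abs,
                    offset_abs_h = onset_abs + s$alpha_h))
  class(out) <- c("rk_activity", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Double-plotted actogram
#'
#' The standard chronobiology display: each row shows two consecutive days,
#' with activity as vertical bars.
#'
#' @param record An activity record (see [simulate_actogram()]).
#' @return A ggplot object.
#' @export
plot_actogram <- function(record) {
  bin_h <- attr(record, "bin_h") %||% median(diff(record$time_h))
  df <- tibble(day = floor(record$time_h / 24),
               hour = record$time_h %% 24,
               counts = record$counts)
  df2 <- bind_rows(
    mutate(df, row = .data$day, x = .data$hour),
    mutate(df, row = .data$day - 1, x = .data$hour + 24))
  df2 <- df2[df2$row >= 0 & df2$row <= max(df$day) - 1 & df2$counts > 0, ]
  q90 <- quantile(df$counts[df$counts > 0], 0.9, names = FALSE)
  df2$bar <- 0.9 * pmin(1, df2$counts / max(1, q90))
  ggplot2::ggplot(df2) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$row + 0.95,
                                       yend = .data$row + 0.95 - .data$bar),
                          linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 12)) +
    ggplot2::labs(x = "Time (h, double plotted)", y = "Day")
}
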