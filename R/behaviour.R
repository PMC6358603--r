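# Wheel-running actogram analysis: chi-squared periodogram, activity onsets
# and offsets, phase angle of entrainment, alpha, re-entrainment PS50 and
# Aschoff Type II light-pulse shifts.

#' Chi-squared periodogram (Sokolove-Bushell)
#'
#' For each trial period `P` (folded over `K = round(P / bin)` columns) the
#' statistic is the between-column sum of squares of the folded means over
#' the pooled variance,
#' `Qp = sum_h n_h (M_h - M)^2 / (sum_i (x_i - M)^2 / N)`,
#' approximately chi-squared with `K - 1` df under the null of no
#' periodicity. The significance line is the chi-squared quantile at level
#' `alpha`, Bonferroni-corrected for the number of trial periods scanned
#' (as actigraphy packages draw it; without the correction an 80-period
#' scan crosses its own line far more often than `alpha` suggests). The
#' best period is the `Qp` maximum above the line.
#'
#' @param record Activity record tibble with columns `time_h` and `counts`
#'   (see [simulate_actogram()]).
#' @param band Period search band in hours (default 20-28).
#' @param step_h Trial-period step (default 0.1 h, matching 6-min bins).
#' @param alpha Family-wise significance level of the threshold line.
#' @param correct `"bonferroni"` (default) corrects the line for the number
#'   of trial periods; `"none"` draws it at raw `alpha` per period.
#' @param bin_h Bin width in hours; taken from the record attribute when
#'   absent.
#'
#' @return An object of class `rk_periodogram`: the per-period table
#'   (`period_h`, `qp`, `df`, `significance`), `best_period_h` (NA when no
#'   period crosses the line) and the settings. [tidy()] returns the table,
#'   [glance()] the summary.
#' @export
#'
#' @examples
#' rec <- simulate_actogram(n_days = 10)
#' glance(chi_sq_periodogram(rec))
chi_sq_periodogram <- function(record, band = c(20, 28), step_h = 0.1,
                               alpha = 0.001,
                               correct = c("bonferroni", "none"),
                               bin_h = NULL) {
  correct <- match.arg(correct)
  bin_h <- bin_h %||% attr(record, "bin_h") %||% median(diff(record$time_h))
  x <- record$counts
  N <- length(x)
  if (N * bin_h < 2 * band[2]) {
    abort("record must span at least twice the longest trial period")
  }
  ks <- unique(round(seq(band[1], band[2], by = step_h) / bin_h))
  ks <- ks[ks >= 2 & ks <= floor(N / 2)]
  alpha_line <- if (correct == "bonferroni") alpha / length(ks) else alpha
  M <- mean(x)
  denom <- sum((x - M)^2) / N
  rows <- purrr::map_dfr(ks, function(K) {
    h <- (seq_len(N) - 1) %% K
    M_h <- rowsum(x, h) / tabulate(h + 1, K)
    n_h <- tabulate(h + 1, K)
    qp <- sum(n_h * (M_h - M)^2) / denom
    tibble(period_h = K * bin_h, qp = qp, df = K - 1,
           significance = qchisq(1 - alpha_line, K - 1))
  })
  above <- rows$qp > rows$significance
  best <- if (any(above)) rows$period_h[which.max(rows$qp * above)] else NA_real_
  structure(list(table = rows, best_period_h = best, alpha = alpha,
                 correct = correct, band = band, bin_h = bin_h),
            class = "rk_periodogram")
}

#' @method print rk_periodogram
#' @export
print.rk_periodogram <- function(x, ...) {
  cat(sprintf("<rk_periodogram> band %.1f-%.1f h, best period %s\n",
              x$band[1], x$band[2],
              if (is.na(x$best_period_h)) "none above the significance line"
              else sprintf("%.2f h", x$best_period_h)))
  invisible(x)
}

#' @method tidy rk_periodogram
#' @export
tidy.rk_periodogram <- function(x, ...) x$table

#' @method glance rk_periodogram
#' @export
glance.rk_periodogram <- function(x, ...) {
  i <- which.max(x$table$qp)
  tibble(best_period_h = x$best_period_h, max_qp = x$table$qp[i],
         significance_at_max = x$table$significance[i], alpha = x$alpha)
}

#' @method autoplot rk_periodogram
#' @export
autoplot.rk_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$significance),
                       linetype = "dashed", colour = "red3") +
    ggplot2::labs(x = "Trial period (h)", y = expression(Q[p]),
                  title = if (is.na(object$best_period_h)) "No significant period"
                  else sprintf("Best period %.2f h", object$best_period_h))
}

#' Detect daily activity onsets and offsets
#'
#' Scans the record on the absolute timeline for activity starts and ends.
#' A bin is active when its count reaches `threshold_frac` of the peak of
#' the 1 h forward-smoothed counts for that calendar day. An onset is an
#' inactive-to-active transition confirmed by at least `confirm_frac` active
#' bins over the following `confirm_h` hours; an offset is the mirror-image
#' criterion running backwards. Events closer than `min_separation_h` to
#' the previous event of the same kind are ignored. These thresholds mimic
#' common actogram-scoring defaults and are all adjustable.
#'
#' @inheritParams chi_sq_periodogram
#' @param threshold_frac Activity threshold as a fraction of the day's
#'   smoothed peak (default 0.2).
#' @param smooth_h Forward smoothing window (h).
#' @param confirm_h,confirm_frac Confirmation window (h) and the minimum
#'   fraction of active bins within it.
#' @param min_separation_h Minimum spacing between successive onsets (h).
#'
#' @return A tibble with one row per detected activity bout: `cycle`,
#'   `day` (calendar day of the onset), `onset_abs_h`, `onset_clock_h`,
#'   `offset_abs_h`, `offset_clock_h`, `alpha_h`. Days without a confirmed
#'   onset are simply absent (never interpolated).
#' @export
detect_onsets_offsets <- function(record, threshold_frac = 0.2, smooth_h = 1,
                                  confirm_h = 3, confirm_frac = 0.5,
                                  min_separation_h = 16, bin_h = NULL) {
  bin_h <- bin_h %||% attr(record, "bin_h") %||% median(diff(record$time_h))
  x <- record$counts
  tb <- record$time_h
  n <- length(x)
  sw <- max(1, round(smooth_h / bin_h))
  cw <- max(1, round(confirm_h / bin_h))
  s <- forward_average(x, sw)

  # per-calendar-day threshold: 20% of that day's smoothed peak
  day <- floor(tb / 24)
  peak_by_day <- tapply(s, day, max)
  thr <- threshold_frac * as.numeric(peak_by_day[as.character(day)])
  active <- x >= thr & thr > 0

  run_frac_fwd <- forward_average(as.numeric(active), cw)
  rev_active <- rev(as.numeric(active))
  run_frac_bwd <- rev(forward_average(rev_active, cw))

  onset_idx <- which(active & c(TRUE, !active[-n]) & run_frac_fwd >= confirm_frac)
  offset_idx <- which(active & c(!active[-1], TRUE) & run_frac_bwd >= confirm_frac)

  keep_sep <- function(idx) {
    out <- integer(0)
    last <- -Inf
    for (i in idx) {
      if (tb[i] - last >= min_separation_h) {
        out <- c(out, i)
        last <- tb[i]
      }
    }
    out
  }
  onset_idx <- keep_sep(onset_idx)
  if (length(onset_idx) == 0) {
    return(tibble(cycle = integer(0), day = integer(0),
                  onset_abs_h = numeric(0), onset_clock_h = numeric(0),
                  offset_abs_h = numeric(0), offset_clock_h = numeric(0),
                  alpha_h = numeric(0)))
  }

  purrr::map_dfr(seq_along(onset_idx), function(ci) {
    oi <- onset_idx[ci]
    upper <- if (ci < length(onset_idx)) onset_idx[ci + 1] else n + 1
    offs <- offset_idx[offset_idx >= oi & offset_idx < upper]
    # a bout running into the end of the record has no observable offset
    off_t <- if (length(offs) && max(offs) < n) tb[max(offs)] + bin_h else NA_real_
    tibble(cycle = ci, day = as.integer(floor(tb[oi] / 24)),
           onset_abs_h = tb[oi], onset_clock_h = tb[oi] %% 24,
           offset_abs_h = off_t, offset_clock_h = off_t %% 24,
           alpha_h = off_t - tb[oi])
  })
}

#' Phase angle of entrainment
#'
#' Signed interval between lights-off and activity onset, averaged over
#' entrained days: positive when onset precedes lights-off, negative when
#' activity starts after lights-off.
#'
#' @param record Activity record carrying a `schedule` attribute (per-day
#'   `mode` and `lights_off_h`), as produced by [simulate_actogram()].
#' @param onsets Onset table from [detect_onsets_offsets()]; computed from
#'   `record` when omitted.
#' @param days Days to average over (default: all LD days in the schedule).
#'
#' @return A one-row tibble with `phase_angle_min` and `n_days`.
#' @export
phase_angle <- function(record, onsets = NULL, days = NULL) {
  sched <- attr(record, "schedule")
  check_that(!is.null(sched), "record", "must carry a `schedule` attribute")
  if (is.null(onsets)) onsets <- detect_onsets_offsets(record)
  ld <- sched[sched$mode == "LD", ]
  if (!is.null(days)) ld <- ld[ld$day %in% days, ]
  m <- left_join(ld, onsets, by = "day")
  m <- m[is.finite(m$onset_clock_h), ]
  if (nrow(m) == 0) abort("no detected onsets on entrained days")
  ang <- wrap_signed(m$lights_off_h - m$onset_clock_h, 24) * 60
  tibble(phase_angle_min = mean(ang), n_days = nrow(m))
}

#' Mean daily activity duration (alpha)
#'
#' @param onsets Onset/offset table from [detect_onsets_offsets()].
#' @return A one-row tibble with `alpha_h` (mean onset-to-offset duration,
#'   modulo 24 h) and `n_days`.
#' @export
activity_alpha <- function(onsets) {
  a <- onsets$alpha_h[is.finite(onsets$alpha_h)]
  if (length(a) == 0) abort("no complete activity bouts")
  tibble(alpha_h = mean(a %% 24), n_days = length(a))
}

# Unwrap clock-hour markers so day-to-day changes stay within half a day.
unwrap_clock <- function(x, period = 24) {
  out <- x
  for (i in seq_along(x)[-1]) {
    out[i] <- out[i - 1] + wrap_signed(x[i] - x[i - 1], period)
  }
  out
}

#' Sigmoid fit of re-entrainment (PS50)
#'
#' Fits a 4-parameter logistic to daily phase markers (activity onsets for
#' an advance, offsets for a delay) against days since a schedule shift:
#' `marker(day) = lower + (upper - lower) / (1 + exp(-slope (day - mid)))`.
#' The PS50 - the day at which half the shift is completed - is the fitted
#' midpoint. Markers are unwrapped across midnight before fitting.
#'
#' @param markers Data frame with columns `day` and `marker_h` (clock
#'   hours).
#' @return An object of class `rk_ps50` with `ps50_day`, `asymptotes`,
#'   `slope` and `rss`. Non-convergence raises an error carrying residual
#'   diagnostics. [glance()] returns the one-row summary.
#' @export
#'
#' @examples
#' d <- 0:12
#' m <- 18 + 8 / (1 + exp(-1.2 * (d - 4)))
#' glance(fit_ps50(data.frame(day = d, marker_h = m)))
fit_ps50 <- function(markers) {
  check_that(all(c("day", "marker_h") %in% names(markers)), "markers",
             "must have columns `day` and `marker_h`")
  df <- markers[is.finite(markers$marker_h), ]
  if (nrow(df) < 5) abort("need at least 5 markers for a sigmoid fit")
  df <- df[order(df$day), ]
  y <- unwrap_clock(df$marker_h)
  d <- df$day
  lo0 <- mean(utils::head(y, 2))
  hi0 <- mean(utils::tail(y, 2))
  # steepest day-to-day change anchors the midpoint start; several slope
  # starts guard against singular gradients on step-like data
  mid_steep <- d[which.max(abs(diff(y) / diff(d)))] + 0.5
  fit <- NULL
  last_err <- NULL
  for (start in c(list(list(lo = lo0, hi = hi0, k = 1, mid = median(d)),
                       list(lo = lo0, hi = hi0, k = 2, mid = mid_steep),
                       list(lo = lo0, hi = hi0, k = 0.5, mid = median(d)),
                       list(lo = lo0, hi = hi0, k = 6, mid = mid_steep)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lo + (hi - lo) / (1 + exp(-k * (d - mid))),
        data = data.frame(y = y, d = d),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        last_err <<- e
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # step-like re-entrainment leaves the slope unidentifiable (the sigmoid
    # gradient is singular); fall back to the interpolated half-shift
    # crossing, the construction the sigmoid generalises
    half <- (y[1] + y[length(y)]) / 2
    reached <- if (y[length(y)] >= y[1]) y >= half else y <= half
    if (any(reached) && !all(reached)) {
      i <- min(which(reached))
      cross <- approx(y[c(i - 1, i)], d[c(i - 1, i)], xout = half)$y
      warn("PS50 sigmoid degenerate; midpoint taken from linear interpolation")
      return(structure(list(ps50_day = cross,
                            asymptotes = c(lower = y[1],
                                           upper = y[length(y)]),
                            slope = Inf, rss = 0, n = nrow(df), fit = NULL),
                       class = "rk_ps50"))
    }
    abort(paste0("PS50 sigmoid did not converge: ",
                 conditionMessage(last_err),
                 sprintf(" (marker range %.2f-%.2f h over days %g-%g)",
                         min(y), max(y), min(d), max(d))))
  }
  cf <- unname(coef(fit))  # lo, hi, k, mid
  if (cf[4] < min(d) || cf[4] > max(d)) {
    warn("fitted PS50 midpoint lies outside the observed day range")
  }
  structure(list(ps50_day = cf[4], asymptotes = c(lower = cf[1], upper = cf[2]),
                 slope = cf[3], rss = sum(stats::residuals(fit)^2),
                 n = nrow(df), fit = fit),
            class = "rk_ps50")
}

#' @method print rk_ps50
#' @export
print.rk_ps50 <- function(x, ...) {
  cat(sprintf("<rk_ps50> PS50 at day %.2f (%.2f -> %.2f h, slope %.2f/day)\n",
              x$ps50_day, x$asymptotes[1], x$asymptotes[2], x$slope))
  invisible(x)
}

#' @method glance rk_ps50
#' @export
glance.rk_ps50 <- function(x, ...) {
  tibble(ps50_day = x$ps50_day, lower_h = unname(x$asymptotes[1]),
         upper_h = unname(x$asymptotes[2]), slope = x$slope, rss = x$rss,
         n = x$n)
}

#' Phase shift from an Aschoff Type II light pulse
#'
#' Estimates the phase shift produced by a light pulse followed by release
#' into constant darkness: regression lines are fitted to the activity
#' onsets of at least `n_pre` days before the pulse (the entrained phase)
#' and `n_post` stable days after it (excluding `exclude_days` transient
#' cycles), both extrapolated to the pulse day. The shift is the difference
#' of the extrapolations, with delays negative. Because the post-pulse line
#' has its own slope, free-running drift (tau != 24 h) does not bias the
#' estimate.
#'
#' @param onsets Onset table from [detect_onsets_offsets()].
#' @param pulse_day Calendar day (0-based) on which the pulse was given.
#' @param n_pre,n_post Number of onsets used on each side.
#' @param exclude_days Transient cycles dropped after the pulse.
#'
#' @return A one-row tibble with `shift_h` (negative = delay),
#'   `pre_slope_h_per_day`, `post_slope_h_per_day` and the onset counts.
#' @export
light_pulse_shift <- function(onsets, pulse_day, n_pre = 5, n_post = 5,
                              exclude_days = 2) {
  pre <- onsets[onsets$day < pulse_day, ]
  post <- onsets[onsets$day >= pulse_day + 1 + exclude_days, ]
  pre <- utils::tail(pre, n_pre)
  post <- utils::head(post, n_post)
  if (nrow(pre) < n_pre) abort("too few pre-pulse onsets")
  if (nrow(post) < n_post) abort("too few stable post-pulse onsets")
  y_pre <- unwrap_clock(pre$onset_clock_h)
  y_post <- unwrap_clock(post$onset_clock_h)
  fit_pre <- lm(y_pre ~ day, data = data.frame(day = pre$day))
  fit_post <- lm(y_post ~ day, data = data.frame(day = post$day))
  at <- data.frame(day = pulse_day)
  pred_pre <- predict(fit_pre, at)
  pred_post <- predict(fit_post, at)
  # a delay moves post-pulse onsets to later clock times -> negative shift
  shift <- wrap_signed(pred_pre - pred_post, 24)
  tibble(shift_h = unname(shift),
         pre_slope_h_per_day = unname(coef(fit_pre)[2]),
         post_slope_h_per_day = unname(coef(fit_post)[2]),
         n_pre = nrow(pre), n_post = nrow(post))
}
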