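# FFT-seeded nonlinear least-squares fit of a damped cosine, the workhorse
# rhythm estimator (the "FFT-NLLS" of circadian bioluminescence analysis).

rhythm_fit <- function(period_h = NA_real_, amplitude = NA_real_,
                       phase_peak_h = NA_real_, damping_rate = NA_real_,
                       rae = 1, window = c(NA_real_, NA_real_),
                       residual_sd = NA_real_, arrhythmic = TRUE,
                       n = 0L, fit = NULL) {
  structure(list(period_h = period_h, amplitude = amplitude,
                 phase_peak_h = phase_peak_h, damping_rate = damping_rate,
                 rae = rae, window = window, residual_sd = residual_sd,
                 arrhythmic = arrhythmic, n = n, fit = fit),
            class = "rhythm_fit")
}

#' Fit a damped cosine to a trace (FFT-NLLS)
#'
#' Estimates circadian period, amplitude, peak phase, damping and the relative
#' amplitude error (RAE) of one trace window. The dominant Fourier component
#' within the circadian search band of the linearly detrended signal seeds a
#' nonlinear least-squares fit of
#'
#' `y(t) = c0 + c1 t + A exp(-lambda (t - t_w)) cos(2 pi (t - phi) / T)`
#'
#' where `t_w` is the window start. RAE is the half-width of the amplitude
#' confidence interval divided by the fitted amplitude, clipped to \[0, 1\]
#' (0 = perfectly determined rhythm, 1 = amplitude indistinguishable from
#' zero). If the spectrum shows no significant peak inside the band (Fisher's
#' g test on the detrended periodogram, p > 0.05) or the fit fails, the result
#' is flagged arrhythmic with `rae = 1` rather than failing silently.
#'
#' @inheritParams detrend_rolling
#' @param window Two-element numeric `(start_h, end_h)` restricting the fit,
#'   or `NULL` for the full trace. Must span at least two putative cycles.
#' @param band Circadian period search band in hours (default 16-32 h).
#' @param conf_level Confidence level used for the amplitude interval behind
#'   RAE (default 0.95).
#'
#' @return An object of class `rhythm_fit` with elements `period_h`,
#'   `amplitude` (at window start), `phase_peak_h` (absolute time of the
#'   fitted peak nearest the window start), `damping_rate`, `rae`, `window`,
#'   `residual_sd`, `arrhythmic` and `n`. [tidy()] returns the parameter
#'   table, [glance()] a one-row summary.
#' @export
#'
#' @examples
#' tr <- simulate_ensemble(duration_h = 120, period_h = 24.5, noise_sd = 0,
#'                         damping_rate = 0)
#' glance(fit_fftnlls(tr))
fit_fftnlls <- function(trace, window = NULL, band = c(16, 32),
                        conf_level = 0.95) {
  trace <- as_trace(trace, treatment_time_h = trace_treatment_time(trace))
  if (!is.null(window)) {
    trace_w <- trace[trace$time_h >= window[1] & trace$time_h <= window[2], ]
  } else {
    trace_w <- trace
    window <- range(trace$time_h)
  }
  t <- trace_w$time_h
  y <- trace_w$value
  n <- length(t)
  dt <- trace_dt(trace)
  span <- t[n] - t[1]
  if (span < 2 * band[1]) {
    abort("fit window must span at least two putative cycles")
  }

  # linear detrend, then the periodogram
  tt <- t - t[1]
  lin <- lm(y ~ tt)
  r <- stats::residuals(lin)
  X <- fft(r)
  half <- 2:(floor(n / 2))
  freq <- (half - 1) / (n * dt)
  per <- 1 / freq
  pow <- Mod(X[half])^2
  in_band <- per >= band[1] & per <= band[2]
  if (!any(in_band)) {
    return(rhythm_fit(window = window, n = n,
                      residual_sd = sd(r)))
  }

  # Fisher's g: is the strongest band component more than noise?
  g <- max(pow[in_band]) / sum(pow)
  m <- length(pow)
  p_g <- min(1, m * (1 - g)^(m - 1))
  if (!is.finite(p_g) || p_g > 0.05) {
    return(rhythm_fit(window = window, n = n, residual_sd = sd(r)))
  }

  k <- half[in_band][which.max(pow[in_band])]
  T0 <- 1 / ((k - 1) / (n * dt))
  A0 <- 2 * Mod(X[k]) / n
  theta <- Arg(X[k])
  # r_j ~ A0 cos(2 pi (k-1) j / n + theta): peak offset from window start
  phi0 <- (-theta * T0 / (2 * pi)) %% T0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c0 + c1 * tt + A * exp(-lam * tt) * cos(2 * pi * (tt - phi) / Tp),
      data = data.frame(y = y, tt = tt),
      start = list(c0 = coef(lin)[[1]], c1 = coef(lin)[[2]], A = A0,
                   lam = 0.005, phi = phi0, Tp = T0),
      lower = c(-Inf, -Inf, 0, -0.05, phi0 - T0, band[1]),
      upper = c(Inf, Inf, Inf, 0.5, phi0 + T0, band[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(rhythm_fit(window = window, n = n, residual_sd = sd(r)))
  }

  # parameter order fixed by `start`: c0, c1, A, lam, phi, Tp
  cf <- unname(coef(fit))
  A_hat <- cf[3]; lam_hat <- cf[4]; phi_hat <- cf[5]; T_hat <- cf[6]
  se_A <- tryCatch(unname(sqrt(diag(vcov(fit)))[3]),
                   error = function(e) NA_real_)
  df_res <- n - length(cf)
  halfwidth <- qt(1 - (1 - conf_level) / 2, df_res) * se_A
  rae <- if (is.finite(halfwidth) && A_hat > 0) {
    min(1, max(0, halfwidth / A_hat))
  } else 1

  # peak of exp(-lam s) cos(w (s - phi)) sits atan(lam/w)/w before the cosine
  # peak; report the fitted peak nearest the window start in absolute time
  w <- 2 * pi / T_hat
  delta <- -atan(lam_hat / w) / w
  peak0 <- (phi_hat + delta) %% T_hat
  rhythm_fit(period_h = T_hat, amplitude = A_hat,
             phase_peak_h = t[1] + peak0, damping_rate = lam_hat,
             rae = rae, window = window,
             residual_sd = sd(stats::residuals(fit)),
             arrhythmic = FALSE, n = n, fit = fit)
}

#' @method print rhythm_fit
#' @export
print.rhythm_fit <- function(x, ...) {
  if (x$arrhythmic) {
    cat("<rhythm_fit> arrhythmic (rae = 1), window",
        sprintf("[%.1f, %.1f] h\n", x$window[1], x$window[2]))
  } else {
    cat(sprintf(
      "<rhythm_fit> period %.2f h, amplitude %.1f, peak at %.2f h, rae %.3f\n",
      x$period_h, x$amplitude, x$phase_peak_h, x$rae))
  }
  invisible(x)
}

#' @method tidy rhythm_fit
#' @export
tidy.rhythm_fit <- function(x, ...) {
  if (x$arrhythmic || is.null(x$fit)) {
    return(tibble(term = character(0), estimate = numeric(0),
                  std.error = numeric(0)))
  }
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @method glance rhythm_fit
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble(period_h = x$period_h, amplitude = x$amplitude,
         phase_peak_h = x$phase_peak_h, damping_rate = x$damping_rate,
         rae = x$rae, residual_sd = x$residual_sd,
         arrhythmic = x$arrhythmic, n = x$n,
         window_start_h = x$window[1], window_end_h = x$window[2])
}
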