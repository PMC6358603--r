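#' Rayleigh test of phase coherence
#'
#' Converts per-cell peak phases (in hours) to angles on the circadian
#' circle, and summarises their coherence by the mean resultant length
#' `R = |mean(exp(i theta))|`: 1 when all cells peak together, 0 for
#' phases spread uniformly (or in balanced opposition). The p value for the
#' null of uniformity uses the standard Rayleigh approximation
#' `p = exp(-Z) (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`
#' with `Z = n R^2`, which is accurate for moderate n and flagged
#' approximate below n = 50.
#'
#' @param phases_h Phases in hours (e.g. fitted peak times modulo the
#'   period), length >= 2.
#' @param period_h Period mapping hours to angle (default 24).
#'
#' @return An object of class `rk_rayleigh` with `mean_phase_rad`,
#'   `mean_phase_h`, `R`, `n`, `p_value` and `approx` (TRUE when n < 50).
#'   [glance()] returns the one-row summary.
#' @export
#'
#' @examples
#' rayleigh_test(c(0, 0.5, 23.6, 0.2), period_h = 24)
rayleigh_test <- function(phases_h, period_h = 24) {
  phases_h <- phases_h[is.finite(phases_h)]
  n <- length(phases_h)
  check_that(n >= 2, "phases_h", "need at least 2 phases")
  check_that(period_h > 0, "period_h", "must be > 0")
  theta <- 2 * pi * phases_h / period_h
  cm <- mean(cos(theta))
  sm <- mean(sin(theta))
  R <- sqrt(cm^2 + sm^2)
  mean_rad <- atan2(sm, cm)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(1, max(0, p))
  structure(list(mean_phase_rad = mean_rad,
                 mean_phase_h = (mean_rad * period_h / (2 * pi)) %% period_h,
                 R = R, n = n, p_value = p, approx = n < 50,
                 period_h = period_h, phases_h = phases_h),
            class = "rk_rayleigh")
}

#' @method print rk_rayleigh
#' @export
print.rk_rayleigh <- function(x, ...) {
  cat(sprintf("<rk_rayleigh> R = %.3f, mean phase %.2f h, n = %d, p = %.3g%s\n",
              x$R, x$mean_phase_h, x$n, x$p_value,
              if (x$approx) " (small-n approximation)" else ""))
  invisible(x)
}

#' @method glance rk_rayleigh
#' @export
glance.rk_rayleigh <- function(x, ...) {
  tibble(R = x$R, mean_phase_rad = x$mean_phase_rad,
         mean_phase_h = x$mean_phase_h, n = x$n, p_value = x$p_value,
         approx = x$approx)
}

#' @method autoplot rk_rayleigh
#' @export
autoplot.rk_rayleigh <- function(object, ...) {
  df <- tibble(phase_h = object$phases_h %% object$period_h)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_h)) +
    ggplot2::geom_point(ggplot2::aes(y = 1), alpha = 0.6,
                        position = ggplot2::position_jitter(height = 0.02)) +
    ggplot2::annotate("segment", x = object$mean_phase_h, xend = object$mean_phase_h,
                      y = 0, yend = object$R, linewidth = 1, colour = "red3",
                      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(limits = c(0, object$period_h),
                                breaks = seq(0, object$period_h, by = 6)) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "Phase (h)", y = NULL,
                  title = sprintf("Rayleigh plot: R = %.2f, n = %d",
                                  object$R, object$n))
}
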