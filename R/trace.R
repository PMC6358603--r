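#' Luminescence trace container
#'
#' A trace is a tibble with columns `time_h` (hours, uniform grid) and `value`
#' (counts per second or arbitrary reporter units), optionally a logical
#' `treated` column, carrying the sampling interval and treatment time as
#' attributes. All rhythm metrics in the package accept these tibbles; plain
#' data frames with `time_h`/`value` columns are upgraded on the fly.
#'
#' @param x A data frame with numeric columns `time_h` and `value`.
#' @param treatment_time_h Time of drug treatment in hours, or `NULL` if the
#'   recording is untreated.
#' @param label Optional free-text label for the recording.
#'
#' @return A tibble of class `rk_trace` with attributes `dt_h`,
#'   `treatment_time_h` and `label`.
#' @export
#'
#' @examples
#' tr <- as_trace(data.frame(time_h = seq(0, 72, 0.1),
#'                           value = cos(2 * pi * seq(0, 72, 0.1) / 24)))
#' trace_dt(tr)
as_trace <- function(x, treatment_time_h = NULL, label = NULL) {
  check_that(is.data.frame(x), "x", "must be a data frame")
  check_that(all(c("time_h", "value") %in% names(x)), "x",
             "must have columns `time_h` and `value`")
  t <- x$time_h
  check_that(length(t) >= 2 && all(diff(t) > 0), "time_h",
             "must be strictly increasing with at least 2 samples")
  dts <- diff(t)
  check_that(max(dts) - min(dts) < 1e-6, "time_h",
             "must be uniformly spaced (within 1e-6 h)")
  out <- as_tibble(x)
  attr(out, "dt_h") <- median(dts)
  attr(out, "treatment_time_h") <- treatment_time_h
  attr(out, "label") <- label
  class(out) <- c("rk_trace", class(out))
  out
}

#' @rdname as_trace
#' @export
trace_dt <- function(x) {
  dt <- attr(x, "dt_h")
  if (is.null(dt)) dt <- median(diff(x$time_h))
  dt
}

#' @rdname as_trace
#' @export
trace_treatment_time <- function(x) attr(x, "treatment_time_h")

# Resolve the treatment time from an explicit argument or the trace attribute.
resolve_t0 <- function(trace, treatment_time_h, required = TRUE) {
  t0 <- if (is.null(treatment_time_h)) trace_treatment_time(trace) else treatment_time_h
  if (required && is.null(t0)) {
    abort("`treatment_time_h` is not set on the trace and was not supplied")
  }
  t0
}

#' Ground truth attached to a simulated object
#'
#' Simulated traces, image stacks, actograms and expression sets carry the
#' generating parameters and derived quantities (e.g. noiseless peak times,
#' per-cell phases, planted onsets) so that estimators can be validated by
#' parameter recovery.
#'
#' @param x A simulated object produced by one of the `simulate_*()`
#'   generators.
#' @return A list of ground-truth values (contents depend on the generator).
#' @export
sim_truth <- function(x) {
  tr <- attr(x, "truth")
  if (is.null(tr) && is.list(x)) tr <- x$truth
  tr
}

#' @method autoplot rk_trace
#' @export
autoplot.rk_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (h)", y = "Bioluminescence (cps)")
  t0 <- trace_treatment_time(object)
  if (!is.null(t0)) {
    p <- p + ggplot2::geom_vline(xintercept = t0, linetype = "dashed",
                                 colour = "red3")
  }
  p
}
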