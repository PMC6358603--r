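# Internal helpers shared across modules.

# Validation helper: stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "rhythmkit_spec_error")
  }
  invisible(TRUE)
}

# Centred moving average with partial windows at the edges.
# width is in samples and may be even; edges average whatever part of the
# window overlaps the series.
moving_average <- function(x, width) {
  half <- (width - 1) / 2
  lo <- pmax(1L, ceiling(seq_along(x) - half))
  hi <- pmin(length(x), floor(seq_along(x) + half))
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Forward (causal, left-aligned) moving average over `width` samples; the
# trailing edge averages the remaining samples.
forward_average <- function(x, width) {
  n <- length(x)
  hi <- pmin(n, seq_len(n) + width - 1L)
  cs <- cumsum(c(0, x))
  (cs[hi + 1] - cs[seq_len(n)]) / (hi - seq_len(n) + 1)
}

# Map an hour difference onto (-half, half].
wrap_signed <- function(x, period = 24) {
  out <- x %% period
  out[out > period / 2] <- out[out > period / 2] - period
  out
}

# Quadratic (three-point parabolic) refinement of a local maximum at index i.
# Returns the sub-sample offset in index units, clamped to [-1, 1].
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-1, min(1, off))
}
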