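# Single-cell analysis of bioluminescence time-lapse stacks: ROI detection,
# trace extraction, and centre-of-mass descriptors of the spatiotemporal wave.

# 3x3 median despeckle of every frame at once, via a 19-exchange median-of-9
# sorting network on the shifted copies (edges are replicate-padded).
despeckle3x3 <- function(stack) {
  d <- dim(stack)
  H <- d[1]; W <- d[2]
  pad <- stack[c(1, seq_len(H), H), c(1, seq_len(W), W), , drop = FALSE]
  p <- vector("list", 9)
  k <- 0
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1
      p[[k]] <- pad[seq_len(H) + dy, seq_len(W) + dx, , drop = FALSE]
    }
  }
  xch <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  # Paeth's median-of-9 network; the median lands in position 5
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  p[[5]]
}

# Shared preprocessing: per-frame 3x3 median despeckle, then background
# subtraction. For ROI detection the background is the per-pixel temporal
# minimum (deterministic, removes every static structure so only oscillating
# pixels survive); for CoM the background is the global dark level (scalar
# minimum), which preserves static anatomy in the weighting.
preprocess_stack <- function(stack,
                             background = c("temporal_min", "dark_level")) {
  check_that(is.array(stack) && length(dim(stack)) == 3, "stack",
             "must be a height x width x frames array")
  background <- match.arg(background)
  out <- despeckle3x3(stack)
  if (background == "temporal_min") {
    bg <- apply(out, c(1, 2), min)
    sweep(out, c(1, 2), bg, "-")
  } else {
    out - min(out)
  }
}

#' Detect cell-like ROIs in a time-lapse stack
#'
#' Identifies oscillating cells by thresholding the temporal
#' standard-deviation projection of the despeckled, background-subtracted
#' stack: pixels whose intensity varies over time are cells, static
#' background is not. Connected components are filtered to a plausible cell
#' area range.
#'
#' @param stack Numeric array `height x width x frames` (`stack[y, x, f]`).
#' @param k_sd Threshold for the SD projection, in units of its own SD above
#'   its mean (default 1.5).
#' @param min_px,max_px Area limits in pixels for accepted components
#'   (defaults 4-400); oversized static or merged regions are rejected.
#'
#' @return A tibble with one row per ROI (`roi`, `area_px`, `centroid_x_px`,
#'   `centroid_y_px`) and the integer label image as attribute `labels`.
#'   Zero rows (with a warning) if nothing passes the filter.
#' @export
#'
#' @examples
#' ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 48)
#' detect_rois(ses$stack)
detect_rois <- function(stack, k_sd = 1.5, min_px = 4, max_px = 400) {
  check_that(dim(stack)[3] >= 24, "stack", "need at least 24 frames")
  pp <- preprocess_stack(stack)
  d <- dim(pp)
  mat <- matrix(pp, d[1] * d[2], d[3])
  m1 <- rowMeans(mat)
  sdv <- sqrt(pmax(0, rowMeans(mat^2) - m1^2) * d[3] / (d[3] - 1))
  thr <- mean(sdv) + k_sd * sd(sdv)
  mask <- matrix(sdv > thr, d[1], d[2])
  labels <- EBImage::bwlabel(mask)
  n_lab <- max(labels)
  empty <- tibble(roi = integer(0), area_px = integer(0),
                  centroid_x_px = numeric(0), centroid_y_px = numeric(0))
  if (n_lab == 0) {
    warn("no ROIs detected")
    attr(empty, "labels") <- labels
    return(empty)
  }
  areas <- tabulate(labels[labels > 0], n_lab)
  keep <- which(areas >= min_px & areas <= max_px)
  if (length(keep) == 0) {
    warn("no ROIs within the area limits")
    attr(empty, "labels") <- labels * 0L
    return(empty)
  }
  px_x <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  px_y <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  out <- purrr::map_dfr(seq_along(keep), function(i) {
    sel <- labels == keep[i]
    tibble(roi = i, area_px = as.integer(areas[keep[i]]),
           centroid_x_px = mean(px_x[sel]), centroid_y_px = mean(px_y[sel]))
  })
  relab <- labels
  relab[] <- match(labels, keep, nomatch = 0L)
  attr(out, "labels") <- relab
  out
}

#' Extract per-ROI traces from a stack
#'
#' Mean raw intensity over each ROI mask per frame. The result feeds the
#' rhythm estimators unchanged (one [as_trace()] per ROI).
#'
#' @inheritParams detect_rois
#' @param rois ROI table from [detect_rois()] (its `labels` attribute is
#'   used).
#' @param frame_interval_h Hours per frame.
#'
#' @return A tibble in long format: `roi`, `time_h`, `value`.
#' @export
extract_traces <- function(stack, rois, frame_interval_h = 1) {
  labels <- attr(rois, "labels")
  check_that(!is.null(labels), "rois", "must carry a `labels` attribute")
  d <- dim(stack)
  mat <- matrix(stack, d[1] * d[2], d[3])
  t_h <- (seq_len(d[3]) - 1) * frame_interval_h
  purrr::map_dfr(rois$roi, function(id) {
    idx <- which(labels == id)
    vals <- if (length(idx) == 1) mat[idx, ] else colMeans(mat[idx, , drop = FALSE])
    tibble(roi = id, time_h = t_h, value = vals)
  })
}

#' Centre-of-mass trajectory of a stack
#'
#' After despeckling, background subtraction and normalisation, each frame is
#' thresholded (by default at the 20th percentile of its nonzero pixels) and
#' the centre of mass is the intensity-weighted centroid of the
#' supra-threshold pixels. The CoM integrates the phase wave across the
#' slice: as different sub-regions peak in turn, the CoM sweeps along the
#' wave axis once per circadian cycle.
#'
#' @inheritParams extract_traces
#' @param threshold_quantile Per-frame quantile of nonzero pixel intensities
#'   below which pixels are ignored (0-1).
#'
#' @return A tibble with `frame`, `time_h`, `x_px`, `y_px` (NA for empty
#'   frames).
#' @export
com_series <- function(stack, frame_interval_h = 1,
                       threshold_quantile = 0.2) {
  pp <- preprocess_stack(stack, background = "dark_level")
  top <- max(pp)
  if (top > 0) pp <- pp / top
  d <- dim(pp)
  px_x <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  px_y <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
  out <- t(vapply(seq_len(d[3]), function(f) {
    fr <- pp[, , f]
    nz <- fr[fr > 0]
    if (length(nz) == 0) return(c(NA_real_, NA_real_))
    thr <- quantile(nz, threshold_quantile, names = FALSE)
    sel <- fr >= thr
    w <- fr[sel]
    c(sum(w * px_x[sel]) / sum(w), sum(w * px_y[sel]) / sum(w))
  }, numeric(2)))
  tibble(frame = seq_len(d[3]),
         time_h = (seq_len(d[3]) - 1) * frame_interval_h,
         x_px = out[, 1], y_px = out[, 2])
}

#' Mean-cycle path metrics of a CoM trajectory
#'
#' Folds the CoM positions by circadian phase into `n_bins` bins, averages
#' each bin over `n_days` cycles to obtain the mean cycle path, and reports
#' its perimeter (closed polygon length through the binned means) and the
#' orientation of its first principal axis. A coherent spatiotemporal wave
#' yields a long perimeter along the wave axis; a phase-collapsed field
#' yields a path near a point.
#'
#' @param positions CoM tibble from [com_series()] (columns `time_h`,
#'   `x_px`, `y_px`).
#' @param period_h Circadian period used for phase folding (h).
#' @param n_bins Phase bins per cycle (default 24, hourly bins for hourly
#'   frames).
#' @param n_days Number of cycles averaged (default 5).
#' @param start_h Fold from this time onwards (default 0).
#'
#' @return An object of class `rk_com_path` with the binned `mean_cycle`
#'   tibble, `perimeter_px` and `direction_deg` (principal axis, in \[0,
#'   180) degrees, image coordinates). [tidy()] returns the mean cycle,
#'   [glance()] the summary row.
#' @export
com_path_metrics <- function(positions, period_h = 24, n_bins = 24,
                             n_days = 5, start_h = 0) {
  check_that(all(c("time_h", "x_px", "y_px") %in% names(positions)),
             "positions", "must have columns time_h, x_px, y_px")
  p <- positions[stats::complete.cases(positions[, c("x_px", "y_px")]), ]
  p <- p[p$time_h >= start_h & p$time_h < start_h + n_days * period_h, ]
  if (nrow(p) < 3) abort("fewer than 3 usable CoM positions")
  phase <- ((p$time_h - start_h) %% period_h) / period_h
  p$bin <- pmin(floor(phase * n_bins), n_bins - 1)
  mc <- p %>%
    group_by(.data$bin) %>%
    summarise(x_px = mean(.data$x_px), y_px = mean(.data$y_px),
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$bin) %>%
    mutate(phase_h = (.data$bin + 0.5) * period_h / n_bins)

  xy <- cbind(mc$x_px, mc$y_px)
  closed <- rbind(xy, xy[1, , drop = FALSE])
  perimeter <- sum(sqrt(rowSums(diff(closed)^2)))

  cc <- stats::cov(xy)
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  direction <- (atan2(ev[2], ev[1]) * 180 / pi) %% 180

  structure(list(mean_cycle = mc, perimeter_px = perimeter,
                 direction_deg = direction, period_h = period_h,
                 n_bins = n_bins, n_days = n_days),
            class = "rk_com_path")
}

#' @method print rk_com_path
#' @export
print.rk_com_path <- function(x, ...) {
  cat(sprintf("<rk_com_path> perimeter %.2f px, principal axis %.1f deg, %d bins\n",
              x$perimeter_px, x$direction_deg, x$n_bins))
  invisible(x)
}

#' @method tidy rk_com_path
#' @export
tidy.rk_com_path <- function(x, ...) x$mean_cycle

#' @method glance rk_com_path
#' @export
glance.rk_com_path <- function(x, ...) {
  tibble(perimeter_px = x$perimeter_px, direction_deg = x$direction_deg,
         period_h = x$period_h, n_bins = x$n_bins, n_days = x$n_days)
}

#' @method autoplot rk_com_path
#' @export
autoplot.rk_com_path <- function(object, ...) {
  mc <- object$mean_cycle
  mc2 <- rbind(mc, mc[1, ])
  ggplot2::ggplot(mc2, ggplot2::aes(x = .data$x_px, y = .data$y_px)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                              type = "closed")) +
    ggplot2::geom_point(data = mc, ggplot2::aes(colour = .data$phase_h)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "Phase (h)",
                  title = sprintf("Mean CoM cycle path (perimeter %.1f px)",
                                  object$perimeter_px))
}
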