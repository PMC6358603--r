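# Synthetic time-lapse image stacks: a grid of oscillating cells carrying a
# spatial phase gradient, emulating the dorsomedial-to-ventrolateral
# bioluminescence wave of an SCN slice and its re-direction by treatment.

#' Specification of a synthetic oscillating cell field
#'
#' A `grid_nx` by `grid_ny` grid of disc-shaped cells, each oscillating
#' according to a shared [ensemble_spec()] template but with its own phase:
#' the projection of the cell position onto the gradient direction, scaled so
#' the field spans `phase_gradient_span_h` hours, plus Gaussian scatter. If
#' the template carries a treatment and `post_gradient_direction_deg` is set,
#' each cell additionally receives the phase offset that re-directs the wave
#' along the new axis after treatment.
#'
#' Image coordinates follow the usual raster convention: x increases along
#' columns (rightwards), y along rows (downwards); direction angles are
#' measured in that frame, so 0 degrees points along +x and 90 degrees along
#' +y.
#'
#' @param grid_nx,grid_ny Cells per row/column (each >= 2).
#' @param cell_radius_px Disc radius in pixels.
#' @param cell_spacing_px Centre-to-centre spacing in pixels.
#' @param frame_interval_h Hours between frames (1 h as for CCD slice
#'   imaging).
#' @param duration_h Recording length in hours.
#' @param phase_gradient_direction_deg Direction of increasing phase.
#' @param phase_gradient_span_h Phase difference across the field (h, >= 0).
#' @param phase_scatter_sd_h Per-cell phase scatter SD (h).
#' @param post_gradient_direction_deg Gradient direction after treatment, or
#'   `NULL` to keep the pre-treatment wave.
#' @param cell_spec [ensemble_spec()] template shared by all cells (its
#'   `duration_h`/`dt_h` are overridden by the frame grid).
#' @param seed Integer seed.
#'
#' @return A validated list of class `wave_field_spec`.
#' @export
wave_field_spec <- function(grid_nx = 5, grid_ny = 5, cell_radius_px = 4,
                            cell_spacing_px = 12, frame_interval_h = 1,
                            duration_h = 96,
                            phase_gradient_direction_deg = 0,
                            phase_gradient_span_h = 6,
                            phase_scatter_sd_h = 0,
                            post_gradient_direction_deg = NULL,
                            cell_spec = ensemble_spec(duration_h = max(duration_h, 72),
                                                      baseline = 200,
                                                      amplitude = 150),
                            seed = 1L) {
  check_that(grid_nx >= 2 && grid_ny >= 2, "grid_nx/grid_ny",
             "grid dimensions must be >= 2")
  check_that(phase_gradient_span_h >= 0, "phase_gradient_span_h",
             "must be >= 0")
  check_that(cell_radius_px >= 1, "cell_radius_px", "must be >= 1")
  check_that(cell_spacing_px > 2 * cell_radius_px, "cell_spacing_px",
             "cells must not touch (spacing > 2 * radius)")
  check_that(duration_h >= 24, "duration_h",
             "need at least 24 h of frames")
  structure(list(grid_nx = grid_nx, grid_ny = grid_ny,
                 cell_radius_px = cell_radius_px,
                 cell_spacing_px = cell_spacing_px,
                 frame_interval_h = frame_interval_h,
                 duration_h = duration_h,
                 phase_gradient_direction_deg = phase_gradient_direction_deg,
                 phase_gradient_span_h = phase_gradient_span_h,
                 phase_scatter_sd_h = phase_scatter_sd_h,
                 post_gradient_direction_deg = post_gradient_direction_deg,
                 cell_spec = cell_spec, seed = as.integer(seed)),
            class = "wave_field_spec")
}

# Normalised projection of cell positions onto a gradient direction,
# in [0, 1] (all 0.5 when the field is degenerate along that axis).
gradient_offsets <- function(x, y, direction_deg, span_h) {
  u <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
  proj <- x * u[1] + y * u[2]
  rng <- range(proj)
  pn <- if (diff(rng) < 1e-9) rep(0.5, length(proj)) else (proj - rng[1]) / diff(rng)
  span_h * (pn - 0.5)
}

#' Simulate a time-lapse stack of oscillating cells
#'
#' Renders the cell field of a [wave_field_spec()] into a 16-bit image stack
#' (array `height x width x frames`, `stack[y, x, f]`). Each cell is a
#' uniform disc whose intensity follows its own damped-cosine trace; discs do
#' not overlap. Ground truth holds the per-cell positions and phases and the
#' centre of mass of the noiseless field per frame (intensity-weighted, no
#' threshold).
#'
#' @param spec A [wave_field_spec()], or arguments forwarded to it.
#' @param ... Passed to [wave_field_spec()] when `spec` is missing.
#'
#' @return An object of class `rk_imaging`: a list with `stack`,
#'   `frame_interval_h` and a `truth` list (`spec`, `cells`, `com`).
#' @export
#'
#' @examples
#' ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 48)
#' dim(ses$stack)
simulate_wave_field <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- wave_field_spec(...)
  check_that(inherits(spec, "wave_field_spec"), "spec",
             "must be a `wave_field_spec`")
  s <- spec
  offset <- s$cell_radius_px + 4
  xs <- offset + (seq_len(s$grid_nx) - 1) * s$cell_spacing_px
  ys <- offset + (seq_len(s$grid_ny) - 1) * s$cell_spacing_px
  width <- max(xs) + offset
  height <- max(ys) + offset
  cells <- tidyr::expand_grid(iy = seq_len(s$grid_ny), ix = seq_len(s$grid_nx))
  cells$cell <- seq_len(nrow(cells))
  cells$x_px <- xs[cells$ix]
  cells$y_px <- ys[cells$iy]

  base <- s$cell_spec
  pre_off <- gradient_offsets(cells$x_px, cells$y_px,
                              s$phase_gradient_direction_deg,
                              s$phase_gradient_span_h)
  scatter <- if (s$phase_scatter_sd_h > 0) {
    with_seed(s$seed, rnorm(nrow(cells), 0, s$phase_scatter_sd_h))
  } else {
    rep(0, nrow(cells))
  }
  cells$phase_h <- base$phase_h + pre_off + scatter

  d_phase_extra <- rep(0, nrow(cells))
  if (!is.null(s$post_gradient_direction_deg) &&
      !is.null(base$treatment_time_h)) {
    post_off <- gradient_offsets(cells$x_px, cells$y_px,
                                 s$post_gradient_direction_deg,
                                 s$phase_gradient_span_h)
    # shifting a cell's peaks later (a delay) is a negative d_phase_h
    d_phase_extra <- -(post_off - pre_off)
  }
  cells$d_phase_h <- base$d_phase_h + d_phase_extra

  t <- seq(0, s$duration_h, by = s$frame_interval_h)
  n_f <- length(t)

  # per-cell traces (noise seeded per cell for determinism)
  cell_vals <- matrix(0, nrow(cells), n_f)
  for (i in seq_len(nrow(cells))) {
    cs <- base
    cs$phase_h <- cells$phase_h[i]
    cs$d_phase_h <- cells$d_phase_h[i]
    v <- ensemble_signal(cs, t)
    if (base$noise_sd > 0) {
      v <- v + with_seed(s$seed * 100003L + i, rnorm(n_f, 0, base$noise_sd))
    }
    cell_vals[i, ] <- v
  }

  # disc masks rendered once; frame intensities filled by linear indexing
  px_x <- matrix(rep(seq_len(width), each = height), height, width)
  px_y <- matrix(rep(seq_len(height), times = width), height, width)
  stack <- array(0, dim = c(height, width, n_f))
  clean <- array(0, dim = c(height, width, n_f))
  frame_off <- (seq_len(n_f) - 1) * height * width
  for (i in seq_len(nrow(cells))) {
    mask <- (px_x - cells$x_px[i])^2 + (px_y - cells$y_px[i])^2 <=
      s$cell_radius_px^2
    idx <- which(mask)
    cs <- base
    cs$phase_h <- cells$phase_h[i]
    cs$d_phase_h <- cells$d_phase_h[i]
    v_clean <- ensemble_signal(cs, t)
    all_idx <- rep(idx, times = n_f) + rep(frame_off, each = length(idx))
    stack[all_idx] <- stack[all_idx] + rep(cell_vals[i, ], each = length(idx))
    clean[all_idx] <- clean[all_idx] + rep(v_clean, each = length(idx))
  }
  stack <- round(pmin(pmax(stack, 0), 65535))

  # noiseless centre of mass, intensity weighted over the whole field
  # (clipped at zero exactly as the rendered stack is)
  clean <- pmax(clean, 0)
  com <- t(vapply(seq_len(n_f), function(f) {
    fr <- clean[, , f]
    tot <- sum(fr)
    if (tot <= 0) return(c(NA_real_, NA_real_))
    c(sum(fr * px_x) / tot, sum(fr * px_y) / tot)
  }, numeric(2)))

  structure(
    list(stack = stack, frame_interval_h = s$frame_interval_h,
         truth = list(
           spec = s,
           cells = as_tibble(cells[, c("cell", "x_px", "y_px", "phase_h",
                                       "d_phase_h")]),
           com = tibble(frame = seq_len(n_f), time_h = t,
                        x_px = com[, 1], y_px = com[, 2]))),
    class = "rk_imaging")
}

#' @method print rk_imaging
#' @export
print.rk_imaging <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<rk_imaging> %d x %d px, %d frames at %.2g h\n",
              d[2], d[1], d[3], x$frame_interval_h))
  invisible(x)
}
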