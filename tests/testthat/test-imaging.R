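test_that("synthetic wave fields are deterministic and carry truth", {
  s <- wave_field_spec(grid_nx = 3, grid_ny = 3, duration_h = 48,
                       phase_scatter_sd_h = 0.5, seed = 4L)
  a <- simulate_wave_field(s)
  b <- simulate_wave_field(s)
  expect_identical(a$stack, b$stack)
  expect_equal(nrow(sim_truth(a)$cells), 9)
  expect_error(wave_field_spec(grid_nx = 1), "grid")
})

test_that("zero span and scatter give perfectly coherent truth phases", {
  ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 48,
                             phase_gradient_span_h = 0,
                             phase_scatter_sd_h = 0)
  ph <- sim_truth(ses)$cells$phase_h
  expect_equal(ph, rep(ph[1], length(ph)))
  expect_equal(rayleigh_test(ph)$R, 1, tolerance = 1e-12)
})

test_that("ROI detection finds every oscillating disc with sub-pixel centroids", {
  ses <- simulate_wave_field(grid_nx = 5, grid_ny = 5, duration_h = 96,
                             phase_gradient_span_h = 8)
  rois <- detect_rois(ses$stack)
  cells <- sim_truth(ses)$cells
  expect_equal(nrow(rois), 25)
  err <- vapply(seq_len(nrow(rois)), function(i) {
    min(sqrt((cells$x_px - rois$centroid_x_px[i])^2 +
               (cells$y_px - rois$centroid_y_px[i])^2))
  }, numeric(1))
  expect_lt(max(err), 1)
})

test_that("a uniform constant stack yields no ROIs", {
  stack <- array(100, dim = c(30, 30, 30))
  expect_warning(rois <- detect_rois(stack), "no ROIs")
  expect_equal(nrow(rois), 0)
})

test_that("bright static regions and out-of-range areas are rejected", {
  ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 48)
  stack <- ses$stack
  # a giant bright static region (disjoint from the cells): constant in
  # time, so it carries no temporal variance and must not become an ROI
  d <- dim(stack)
  big <- array(0, dim = c(d[1] + 30, d[2] + 30, d[3]))
  big[seq_len(d[1]), seq_len(d[2]), ] <- stack
  big[(d[1] + 8):(d[1] + 30), (d[2] + 8):(d[2] + 30), ] <- 30000
  rois <- detect_rois(big)
  expect_equal(nrow(rois), 9)
  expect_true(all(rois$area_px <= 400))
  expect_true(all(rois$centroid_x_px <= d[2]))
  # area limits exclude components outside [min_px, max_px]
  expect_warning(none <- detect_rois(big, min_px = 200), "area")
  expect_equal(nrow(none), 0)
})

test_that("single-pixel ROI traces equal that pixel's series", {
  stack <- array(runif(20 * 20 * 30, 0, 100), dim = c(20, 20, 30))
  labels <- matrix(0L, 20, 20)
  labels[7, 13] <- 1L
  rois <- tibble::tibble(roi = 1L, area_px = 1L, centroid_x_px = 13,
                         centroid_y_px = 7)
  attr(rois, "labels") <- labels
  tr <- extract_traces(stack, rois, frame_interval_h = 1)
  expect_equal(tr$value, stack[7, 13, ])
})

test_that("identical discs give identical extracted traces", {
  ses <- simulate_wave_field(grid_nx = 2, grid_ny = 2, duration_h = 48,
                             phase_gradient_span_h = 0)
  rois <- detect_rois(ses$stack)
  tr <- extract_traces(ses$stack, rois, 1)
  wide <- tidyr::pivot_wider(tr, names_from = "roi", values_from = "value")
  expect_equal(wide$`1`, wide$`2`)
})

test_that("per-ROI periods are recovered end to end", {
  ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 96,
                             phase_gradient_span_h = 4)
  rois <- detect_rois(ses$stack)
  tr <- extract_traces(ses$stack, rois, 1)
  periods <- vapply(split(tr, tr$roi), function(d) {
    fit_fftnlls(as_trace(d[, c("time_h", "value")]))$period_h
  }, numeric(1))
  expect_true(all(abs(periods - 24) < 0.2))
})

test_that("CoM of a symmetric static blob sits at its centre every frame", {
  stack <- array(0, dim = c(31, 31, 26))
  for (f in 1:26) stack[14:18, 14:18, f] <- 50
  com <- com_series(stack)
  expect_equal(com$x_px, rep(16, 26), tolerance = 1e-9)
  expect_equal(com$y_px, rep(16, 26), tolerance = 1e-9)
})

test_that("CoM follows the brighter of two blobs", {
  stack <- array(0, dim = c(21, 41, 26))
  for (f in 1:26) {
    w <- (f - 1) / 25
    stack[9:13, 6:10, f] <- 100 * (1 - w) + 10
    stack[9:13, 32:36, f] <- 100 * w + 10
  }
  com <- com_series(stack)
  expect_lt(com$x_px[2], 15)
  expect_gt(com$x_px[25], 26)
  expect_true(all(diff(com$x_px[2:25]) > 0))
})

test_that("CoM is exactly equivariant under image translation", {
  ses <- simulate_wave_field(grid_nx = 3, grid_ny = 3, duration_h = 48,
                             phase_gradient_span_h = 6)
  stack <- ses$stack
  d <- dim(stack)
  dx <- 5; dy <- 3
  shifted <- array(0, dim = d + c(10, 10, 0))
  shifted[(1:d[1]) + dy, (1:d[2]) + dx, ] <- stack
  base <- array(0, dim = d + c(10, 10, 0))
  base[1:d[1], 1:d[2], ] <- stack
  c0 <- com_series(base)
  c1 <- com_series(shifted)
  expect_equal(c1$x_px, c0$x_px + dx, tolerance = 1e-9)
  expect_equal(c1$y_px, c0$y_px + dy, tolerance = 1e-9)
})

test_that("CoM oscillation axis follows the planted gradient direction", {
  ses <- simulate_wave_field(grid_nx = 5, grid_ny = 5, duration_h = 96,
                             phase_gradient_direction_deg = 90,
                             phase_gradient_span_h = 8)
  # oracle: the noiseless-field CoM from the generator itself
  truth_com <- sim_truth(ses)$com
  expect_lt(diff(range(truth_com$x_px)), 0.1)
  expect_gt(diff(range(truth_com$y_px)), 1)
  # measured CoM from the rendered stack
  com <- com_series(ses$stack)
  cp <- com_path_metrics(com, period_h = 24, n_days = 4)
  expect_lt(abs(cp$direction_deg - 90), 15)
})

test_that("static CoM has zero perimeter and a circle converges to 2 pi r", {
  static <- tibble::tibble(time_h = 0:95, x_px = 10, y_px = 12)
  expect_equal(com_path_metrics(static)$perimeter_px, 0)
  r <- 7
  t <- seq(0, 96, by = 0.25)
  circ <- tibble::tibble(time_h = t,
                         x_px = 20 + r * cos(2 * pi * t / 24),
                         y_px = 20 + r * sin(2 * pi * t / 24))
  per <- com_path_metrics(circ, n_bins = 96, n_days = 4)$perimeter_px
  expect_equal(per, 2 * pi * r, tolerance = 0.01)
})

test_that("perimeter is invariant to a temporal cyclic shift", {
  ses <- simulate_wave_field(grid_nx = 4, grid_ny = 4, duration_h = 96,
                             phase_gradient_span_h = 6)
  com <- com_series(ses$stack)[1:96, ] # whole cycles only
  p0 <- com_path_metrics(com, n_days = 4)$perimeter_px
  rolled <- com
  rolled[c("x_px", "y_px")] <- com[c(31:96, 1:30), c("x_px", "y_px")]
  p1 <- com_path_metrics(rolled, n_days = 4)$perimeter_px
  expect_equal(p1, p0, tolerance = 1e-9)
})

test_that("treatment that collapses the gradient shrinks the wave signature", {
  # pre/post fields simulated with the same seed; the post field has no
  # phase gradient (cells in phase), as after a synchronising treatment
  pre <- simulate_wave_field(grid_nx = 4, grid_ny = 4, duration_h = 96,
                             phase_gradient_span_h = 8,
                             phase_scatter_sd_h = 0.3, seed = 21L)
  post <- simulate_wave_field(grid_nx = 4, grid_ny = 4, duration_h = 96,
                              phase_gradient_span_h = 0,
                              phase_scatter_sd_h = 0.3, seed = 21L)
  per_pre <- com_path_metrics(com_series(pre$stack), n_days = 4)$perimeter_px
  per_post <- com_path_metrics(com_series(post$stack), n_days = 4)$perimeter_px
  expect_lt(per_post, per_pre)
  r_pre <- rayleigh_test(sim_truth(pre)$cells$phase_h)$R
  r_post <- rayleigh_test(sim_truth(post)$cells$phase_h)$R
  expect_gt(r_post, r_pre)
})
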