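test_that("phase shift reproduces the worked peak arithmetic", {
  # pre-period 24 h, last pre-peak 96 h; observed post peaks at 124 and
  # 148 h against predicted 120 and 144 h give a 4 h delay, reported -4
  tr <- simulate_ensemble(duration_h = 240, treatment_time_h = 106,
                          d_phase_h = -4, noise_sd = 0)
  expect_equal(phase_shift(tr)$phase_shift_h, -4, tolerance = 0.05)
})

test_that("null treatment gives a null phase shift", {
  tr <- simulate_ensemble(treatment_time_h = 106, noise_sd = 0)
  expect_equal(phase_shift(tr)$phase_shift_h, 0, tolerance = 0.2)
})

test_that("phase shift is equivariant in the planted shift", {
  s1 <- phase_shift(simulate_ensemble(treatment_time_h = 106,
                                      d_phase_h = -1, noise_sd = 0))
  s2 <- phase_shift(simulate_ensemble(treatment_time_h = 106,
                                      d_phase_h = -3, noise_sd = 0))
  expect_equal(s1$phase_shift_h - s2$phase_shift_h, 2, tolerance = 0.02)
})

test_that("phase shift errors name the deficient side", {
  short_pre <- simulate_ensemble(duration_h = 240, treatment_time_h = 40,
                                 noise_sd = 0)
  expect_error(phase_shift(short_pre), "pre-treatment")
  short_post <- simulate_ensemble(duration_h = 150, treatment_time_h = 106,
                                  noise_sd = 0)
  expect_error(phase_shift(short_post), "post-treatment")
})

test_that("growth extrapolation matches the geometric worked example", {
  expect_equal(growth_extrapolate(c(100, 90, 81)), 72.9, tolerance = 1e-9)
  expect_equal(109.35 / growth_extrapolate(c(100, 90, 81)), 1.5,
               tolerance = 1e-9)
  expect_error(growth_extrapolate(c(100, -3, 81)), "positive")
})

test_that("fold induction is exact on a geometric trace", {
  # peaks decay by 0.9 per cycle; the cycle after treatment is scaled 1.5x
  t <- seq(0, 168, 0.1)
  osc <- 100 * 0.9^((t - 12) / 24) * cos(2 * pi * (t - 12) / 24)
  osc[t >= 100] <- osc[t >= 100] * 1.5
  tr <- as_trace(data.frame(time_h = t, value = osc),
                 treatment_time_h = 106)
  expect_equal(fold_induction(tr)$fold_induction, 1.5, tolerance = 1e-3)
})

test_that("fold induction is 1 without a treatment effect", {
  tr <- simulate_ensemble(treatment_time_h = 106, damping_rate = 0,
                          noise_sd = 0)
  expect_equal(fold_induction(tr)$fold_induction, 1, tolerance = 0.01)
})

test_that("planted induction is recovered under damping and noise", {
  folds <- vapply(1:20, function(s) {
    tr <- simulate_ensemble(treatment_time_h = 106, induction_fold = 1.5,
                            damping_rate = 0.01, noise_sd = 5, seed = s)
    fold_induction(tr)$fold_induction
  }, numeric(1))
  expect_equal(mean(folds), 1.5, tolerance = 0.1)
})

test_that("acute induction reads a normalised step correctly", {
  # trace already on the normalised scale (maximum 1): a +0.3 step reads 0.3
  t <- seq(0, 120, 0.1)
  y <- rep(0.7, length(t))
  y[t > 100] <- 1
  tr <- as_trace(data.frame(time_h = t, value = y), treatment_time_h = 100)
  expect_equal(acute_induction(tr)$acute_induction, 0.3, tolerance = 1e-9)
  # constant trace: no induction
  tr0 <- as_trace(data.frame(time_h = t, value = rep(1, length(t))),
                  treatment_time_h = 100)
  expect_equal(acute_induction(tr0)$acute_induction, 0)
})

test_that("acute induction grows with the planted fold on arrhythmic traces", {
  vals <- vapply(c(1.2, 1.5, 2), function(f) {
    tr <- simulate_ensemble(duration_h = 240, amplitude = 0, baseline = 300,
                            treatment_time_h = 106, induction_fold = f,
                            noise_sd = 3, seed = 7)
    acute_induction(tr)$acute_induction
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
})

test_that("rms change is -50% when the post-window signal is halved", {
  t <- seq(0, 240, 0.1)
  y <- 100 + 20 * cos(2 * pi * t / 24) # stationary oscillation
  y[t >= 106] <- 100 + 10 * cos(2 * pi * t[t >= 106] / 24)
  tr <- as_trace(data.frame(time_h = t, value = y), treatment_time_h = 106)
  expect_equal(rms_change(tr)$rms_change_pct, -50, tolerance = 1)
})

test_that("rms change is null for an unchanged stationary signal", {
  set.seed(5)
  t <- seq(0, 240, 0.1)
  y <- 100 + 15 * cos(2 * pi * t / 24) + rnorm(length(t), 0, 2)
  tr <- as_trace(data.frame(time_h = t, value = y), treatment_time_h = 106)
  expect_equal(rms_change(tr)$rms_change_pct, 0, tolerance = 5)
})

test_that("rms change is invariant to overall trace scaling", {
  set.seed(6)
  t <- seq(0, 240, 0.1)
  y <- 100 + 15 * cos(2 * pi * t / 24) + rnorm(length(t), 0, 3)
  y[t >= 106] <- 0.4 * y[t >= 106] + 60
  tr <- as_trace(data.frame(time_h = t, value = y), treatment_time_h = 106)
  tr10 <- as_trace(data.frame(time_h = t, value = 10 * y),
                   treatment_time_h = 106)
  expect_equal(rms_change(tr)$rms_change_pct,
               rms_change(tr10)$rms_change_pct, tolerance = 1e-9)
})

test_that("rms change falls as the post-treatment amplitude scale falls", {
  vals <- vapply(c(0.6, 0.3, 0.1), function(a) {
    tr <- simulate_ensemble(duration_h = 240, treatment_time_h = 106,
                            amp_scale = a, noise_sd = 2, seed = 3)
    rms_change(tr)$rms_change_pct
  }, numeric(1))
  expect_true(all(vals < 0))
  expect_true(all(diff(vals) < 0))
})

test_that("amplitude and period changes recover planted effects", {
  tr <- simulate_ensemble(duration_h = 240, treatment_time_h = 106,
                          amp_scale = 0.5, d_period_h = 1.5,
                          damping_rate = 0.005, noise_sd = 2, seed = 2)
  r <- treatment_response(tr)
  expect_equal(r$d_period_h, 1.5, tolerance = 0.1)
  expect_equal(r$amplitude_change_pct, -50, tolerance = 5)
  # identical fits: exactly zero change
  f <- fit_fftnlls(tr, window = c(10, 106))
  ac <- amplitude_change(f, f)
  expect_equal(ac$amplitude_change_pct, 0)
  expect_equal(ac$period_change_h, 0)
})

test_that("estimator bias is under 10% of the planted effect on a grid", {
  # With a planted period change, peak extrapolation measures the planted
  # phase displacement plus the displacement the new period accumulates over
  # the analysis window; the estimand is derived from the noiseless truth
  # peaks by the same extrapolation arithmetic.
  expected_shift <- function(tr, t0 = 106) {
    pk <- sim_truth(tr)$peaks$peak_time_h
    pre <- pk[pk < t0]
    obs <- pk[pk >= t0 + 36 & pk <= t0 + 96]
    predicted <- max(pre) + seq_len(8) * 24
    -mean(vapply(obs, function(o) o - predicted[which.min(abs(o - predicted))],
                 numeric(1)))
  }
  cases <- list(c(d_phase = -4, d_period = 1.5, amp = 0.1),
                c(d_phase = -2, d_period = 0.5, amp = 0.5))
  for (cs in cases) {
    res <- vapply(1:8, function(s) {
      tr <- simulate_ensemble(duration_h = 240, treatment_time_h = 106,
                              d_phase_h = cs[["d_phase"]],
                              d_period_h = cs[["d_period"]],
                              amp_scale = cs[["amp"]],
                              damping_rate = 0.005, noise_sd = 2, seed = s)
      r <- treatment_response(tr)
      c(r$phase_shift_h, r$d_period_h, r$amplitude_change_pct,
        expected_shift(tr))
    }, numeric(4))
    expect_lt(abs(mean(res[1, ] - res[4, ])), 0.1 * abs(cs[["d_phase"]]))
    expect_lt(abs(mean(res[2, ]) - cs[["d_period"]]),
              0.1 * cs[["d_period"]])
    true_amp_change <- 100 * (cs[["amp"]] - 1)
    expect_lt(abs(mean(res[3, ]) - true_amp_change),
              0.1 * abs(true_amp_change))
  }
})

test_that("response correlation matches closed-form cases", {
  df <- data.frame(x = c(1, 2, 3, 4.5, 6), y = 2 * c(1, 2, 3, 4.5, 6))
  r <- correlate_responses(df, x, y)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_error(correlate_responses(data.frame(x = rep(1, 5), y = 1:5), x, y),
               "constant")
})

test_that("independent variables are nearly uncorrelated at n = 1000", {
  set.seed(8)
  df <- data.frame(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(correlate_responses(df, x, y)$pearson_r), 0.1)
})
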