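test_that("default waveform hits the programmed peak and cycle mean", {
  w <- fx_waveform()
  expect_equal(peak_flow(w), 100, tolerance = 1e-12)
  expect_equal(mean_flow(w), 27.74, tolerance = 0.01 / 27.74)
  expect_equal(w$period, 1.0)
  expect_true(all(w$q >= 0))           # no dicrotic lobe by default
  # exactly one systolic lobe: positive support is a single interval
  pos <- which(w$q > 1e-9)
  expect_identical(pos, seq(min(pos), max(pos)))
})

test_that("half-sine mean flow matches the closed form 2PT/(pi*C)", {
  grid <- expand.grid(P = c(50, 100, 150), Tf = c(0.25, 0.4),
                      C = c(0.8, 1.0, 1.2))
  for (i in seq_len(nrow(grid))) {
    P <- grid$P[i]; Tf <- grid$Tf[i]; C <- grid$C[i]
    w <- make_aortic_waveform(waveform_params(
      peak_flow = P, heart_rate = 60 / C, systolic_duration = Tf,
      n_samples_per_cycle = 2000))
    expect_equal(mean_flow(w), 2 * P * Tf / (pi * C), tolerance = 1e-4)
  }
})

test_that("calibration inverts the closed form and round-trips the mean", {
  expect_equal(calibrate_systolic_duration(100, 27.74, 1.0),
               27.74 * pi / 200, tolerance = 1e-12)
  for (case in list(c(100, 27.74, 1.0), c(80, 20, 0.8), c(120, 60, 1.2))) {
    Tf <- calibrate_systolic_duration(case[1], case[2], case[3])
    w <- make_aortic_waveform(waveform_params(
      peak_flow = case[1], heart_rate = 60 / case[3],
      systolic_duration = Tf, n_samples_per_cycle = 4000))
    expect_equal(mean_flow(w), case[2], tolerance = 1e-4)
  }
  # limiting case: mean near the half-sine feasibility bound fills the cycle
  expect_equal(calibrate_systolic_duration(100, 2 * 100 / pi - 1e-6, 1.0),
               1.0, tolerance = 1e-6)
  expect_error(calibrate_systolic_duration(100, 0, 1.0), "infeasible")
  expect_error(calibrate_systolic_duration(100, 2 * 100 / pi, 1.0),
               "infeasible")
})

test_that("mean flow is linear in peak flow and exact on constant input", {
  m <- vapply(c(50, 100, 200), function(P)
    mean_flow(make_aortic_waveform(waveform_params(
      peak_flow = P, systolic_duration = 0.35))), numeric(1))
  expect_equal(m[2] / m[1], 2, tolerance = 1e-10)
  expect_equal(m[3] / m[1], 4, tolerance = 1e-10)
  expect_equal(mean_flow(constant_waveform(5)), 5.0)
  expect_error(mean_flow(constant_waveform(5, n = 2)), "3 samples")
})

test_that("a dicrotic lobe of area A reduces the mean by A/period", {
  w0 <- make_aortic_waveform(waveform_params(n_samples_per_cycle = 4000))
  wd <- make_aortic_waveform(waveform_params(
    dicrotic_backflow_fraction = 0.05, dicrotic_duration = 0.1,
    n_samples_per_cycle = 4000))
  lobe_area <- 0.05 * 100 * 2 * 0.1 / pi        # depth * 2*D/pi
  expect_equal(mean_flow(w0) - mean_flow(wd), lobe_area, tolerance = 1e-3)
  expect_lt(min(wd$q), 0)
})

test_that("waveform is periodic under integer-cycle shifts", {
  w <- fx_waveform()
  t <- runif(100, 0, 1)
  expect_equal(w$q_fun(t), w$q_fun(t + 3 * w$period), tolerance = 1e-12)
})

test_that("water column converts hydrostatically to mmHg", {
  expect_equal(water_column_to_mmHg(1088), 80.0, tolerance = 0.1 / 80)
  expect_identical(water_column_to_mmHg(0), 0)
  expect_equal(water_column_to_mmHg(13.5951), 1.0)
  expect_error(water_column_to_mmHg(-5), ">= 0")
})

test_that("waveform CSV round trip preserves samples", {
  w <- fx_waveform()
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  w2 <- read_waveform_csv(f)
  expect_equal(w2$q, w$q)
  expect_equal(w2$period, w$period, tolerance = 1e-9)
  expect_equal(mean_flow(w2), mean_flow(w), tolerance = 1e-9)
})

test_that("waveform parameter validation rejects infeasible shapes", {
  expect_error(waveform_params(systolic_duration = 1.2), "systolic")
  expect_error(waveform_params(dicrotic_backflow_fraction = 0.3),
               "dicrotic_backflow_fraction")
  expect_error(waveform_params(peak_flow = -1), "peak_flow")
})
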