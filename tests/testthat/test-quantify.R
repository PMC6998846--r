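# Plane-based flow quantification and the vortex circulation metric.

test_that("plane flow matches closed-form flux for plug and Poiseuille tubes", {
  # plug: uniform v_z = 100 mm/s (10 cm/s) in a 10 mm tube -> 31.42 mL/s
  plug <- analytic_tube_field(R = 10, function(X, Y, Z)
    list(vx = X * 0, vy = Y * 0, vz = X * 0 + 10))
  pl <- plane_spec(c(0, 0, 0), c(0, 0, 1), extent = 12, sampling_step = 0.2)
  expect_equal(plane_flow(plug, pl, 1), pi * 100 * 100 / 1000,
               tolerance = 0.01)
  # Poiseuille: centreline 20 cm/s in a 10 mm tube -> q = 31.416 mL/s
  pois <- analytic_tube_field(R = 10, function(X, Y, Z) {
    s2 <- (X^2 + Y^2) / 100
    list(vx = X * 0, vy = Y * 0, vz = 20 * (1 - s2))
  })
  expect_equal(plane_flow(pois, pl, 1), 31.41593, tolerance = 0.01)
  # zero field
  zero <- analytic_tube_field(R = 10, function(X, Y, Z)
    list(vx = X * 0, vy = Y * 0, vz = Z * 0))
  expect_identical(plane_flow(zero, pl, 1), 0)
  # plane fully outside the grid is an input error
  expect_error(plane_flow(plug, plane_spec(c(200, 200, 0)), 1), "grid")
})

test_that("plane quadrature error decreases as O(step^2)", {
  pois <- analytic_tube_field(R = 10, function(X, Y, Z) {
    s2 <- (X^2 + Y^2) / 100
    list(vx = X * 0, vy = Y * 0, vz = 20 * (1 - s2))
  }, dims = c(96, 96, 12), fov = c(24, 24, 12))
  err <- vapply(c(3.2, 0.8, 0.2), function(st)
    abs(plane_flow(pois, plane_spec(c(0, 0, 0), extent = 12,
                                    sampling_step = st), 1) - 31.41593),
    numeric(1))
  # refinement gains at least the O(step^2) factor until the trilinear
  # interpolation floor of the voxelised field is reached
  expect_lt(err[2], err[1] / 4)
  expect_lt(err[3], err[1] / 4)
  expect_lt(err[3] / 31.41593, 0.001)
})

test_that("synthetic frames carry the programmed instantaneous flux", {
  fld <- fx_field()
  pl <- plane_spec(c(0, 0, 15), extent = 19, sampling_step = 0.4)
  for (k in c(3, 5, 8)) {
    expect_equal(plane_flow(fld, pl, k), fld$q_frames[k],
                 tolerance = 0.02)
  }
})

test_that("quantified metrics satisfy their internal identities", {
  fld <- fx_field_small()
  pl <- plane_spec(c(0, 0, -12), extent = 14, sampling_step = 0.4)
  r <- quantify_plane(fld, pl)
  # net = (forward - backward) / period
  expect_equal(r$net_flow,
               (r$forward_volume - r$backward_volume) / fld$period,
               tolerance = 1e-12)
  # net equals the periodic trapezoid of the per-frame flows
  tt <- c(fld$times, fld$times[1] + fld$period)
  qq <- c(r$q, r$q[1])
  expect_equal(r$net_flow,
               sum(diff(tt) * (qq[-1] + qq[-length(qq)]) / 2) / fld$period,
               tolerance = 1e-12)
  expect_gte(r$peak_flow, r$net_flow)
  expect_identical(r$regurgitant_fraction, 0)   # no backflow programmed
})

test_that("dicrotic backflow produces a positive regurgitant fraction", {
  wd <- make_aortic_waveform(waveform_params(
    dicrotic_backflow_fraction = 0.08, dicrotic_duration = 0.12))
  acq <- default_acquisition(fx_profile(), matrix_size = c(32, 32, 32),
                             n_frames = 16)
  fld <- sample_velocity_field(fx_profile(), wd, acq)
  r <- quantify_plane(fld, plane_spec(c(0, 0, -12), extent = 14,
                                      sampling_step = 0.4))
  expect_gt(r$regurgitant_fraction, 0)
  expect_gt(r$backward_volume, 0)
})

test_that("net flow is conserved between proximal and distal planes", {
  fld <- fx_field()
  pls <- default_planes(fx_profile(), sampling_step = 0.25)
  cc <- conservation_check(fld, pls$proximal, pls$distal)
  expect_lte(cc$relative_difference, 0.02)
  # identical plane twice
  cc0 <- conservation_check(fld, pls$distal, pls$distal)
  expect_identical(cc0$relative_difference, 0)
})

test_that("net flow is invariant to plane position along straight segments", {
  fld <- fx_field()
  nets <- vapply(c(-14, -10, 28, 30, 34), function(z)
    quantify_plane(fld, plane_spec(c(0, 0, z), extent = 19,
                                   sampling_step = 0.3))$net_flow,
    numeric(1))
  expect_lt((max(nets) - min(nets)) / max(nets), 0.02)
})

test_that("noise degrades proximal-distal consistency in expectation", {
  fld <- fx_field_small()
  pls <- default_planes(fx_profile(), sampling_step = 0.5)
  base <- conservation_check(fld, pls$proximal, pls$distal)
  noisy <- vapply(1:4, function(s) {
    nf <- add_noise(fld, 10, seed = s)
    conservation_check(nf, pls$proximal, pls$distal)$relative_difference
  }, numeric(1))
  expect_gt(mean(noisy), base$relative_difference)
})

test_that("aliasing above venc biases net flow; below venc it is exact", {
  fld <- fx_field_small()
  pl <- plane_spec(c(0, 0, -12), extent = 14, sampling_step = 0.5)
  net0 <- quantify_plane(fld, pl)$net_flow
  # below venc: identity
  expect_equal(quantify_plane(apply_pc_roundtrip(fld), pl)$net_flow, net0,
               tolerance = 1e-12)
  # venc below the peak velocity: wrapped velocities bias the flow
  vmax <- max(abs(fld$vz))
  expect_gt(vmax, 30)
  low <- fld; low$venc <- 30
  net_alias <- quantify_plane(apply_pc_roundtrip(low), pl)$net_flow
  expect_gt(abs(net_alias - net0) / abs(net0), 0.05)
})

test_that("sinus circulation recovers the prescribed vortex strength", {
  fld <- fx_field()
  kd <- which(fld$gate == 1)[1]       # diastolic frame, vortex fully on
  ks <- which.max(fld$q_frames)       # systolic peak, vortex gated off
  for (s in 0:2) {
    circ <- sinus_circulation(fld, s, kd)
    expect_equal(circ, vortex_params()$strength, tolerance = 0.05)
  }
  # temporal gating: diastolic circulation dominates the systolic value
  expect_gt(sinus_circulation(fld, 0, kd),
            3 * abs(sinus_circulation(fld, 0, ks)))
  expect_error(sinus_circulation(fld, 5, kd), "sinus_index")
})

test_that("circulation is at the noise floor when the vortex is disabled", {
  acq <- default_acquisition(fx_profile(), matrix_size = c(32, 32, 32),
                             n_frames = 8)
  fld <- sample_velocity_field(fx_profile(), fx_waveform(), acq)
  kd <- which(abs(fld$q_frames) < 1e-12)[1]
  vm <- fx_field()$vortex_meta
  circ <- sinus_circulation(fld, frame = kd, center = vm$centers[1, ],
                            axis = vm$axes[1, ], loop_radius = vm$loop_radius)
  expect_lt(abs(circ), 1e-9)
})
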