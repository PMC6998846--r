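test_that("lumen radius matches the named diameters at the key stations", {
  pr <- fx_profile()
  p <- fx_params()
  th <- seq(0, 2 * pi, length.out = 65)[1:64]
  # annulus plane: exactly annulus radius at all angles
  expect_equal(pr$radius_fn(rep(0, 64), th),
               rep(p$annulus_diameter / 2, 64), tolerance = 1e-12)
  # LVOT and ascending aorta segments
  expect_equal(pr$radius_fn(-p$lvot_length, 1.3), p$lvot_diameter / 2)
  expect_equal(pr$radius_fn(pr$z_max, 2.1),
               p$ascending_aorta_diameter / 2)
  # sinotubular junction (bulge vanished)
  expect_equal(pr$radius_fn(p$sinus_height, 0),
               p$sinotubular_diameter / 2, tolerance = 1e-9)
})

test_that("maximum sinus radius equals sinus_max_diameter/2 to 1e-9 mm", {
  pr <- fx_profile()
  zz <- seq(0, fx_params()$sinus_height, length.out = 20001)
  expect_equal(max(pr$radius_fn(zz, 0)),
               fx_params()$sinus_max_diameter / 2, tolerance = 1e-9)
})

test_that("equal diameters degenerate to a straight tube (no bulge)", {
  pr <- build_root_profile(tube_params())
  expect_equal(pr$bulge_amplitude, 0)
  zz <- runif(50, pr$z_min, pr$z_max)
  th <- runif(50, 0, 2 * pi)
  expect_equal(pr$radius_fn(zz, th), rep(10, 50), tolerance = 1e-12)
})

test_that("radius function is continuous in z and n-fold periodic in theta", {
  pr <- fx_profile()
  zz <- seq(pr$z_min, pr$z_max, length.out = 5000)
  r <- pr$radius_fn(zz, 0.7)
  expect_lt(max(abs(diff(r))), 0.1)   # no jumps at segment boundaries
  # periodicity over the sinus segment
  zs <- runif(40, 0, fx_params()$sinus_height)
  th <- runif(40, 0, 2 * pi)
  expect_equal(pr$radius_fn(zs, th),
               pr$radius_fn(zs, th + 2 * pi / 3), tolerance = 1e-12)
})

test_that("wall thickness does not alter the lumen profile", {
  p1 <- root_params(wall_thickness = 2)
  p2 <- root_params(wall_thickness = 3)
  pr1 <- build_root_profile(p1); pr2 <- build_root_profile(p2)
  zz <- runif(30, pr1$z_min, pr1$z_max); th <- runif(30, 0, 2 * pi)
  expect_equal(pr1$radius_fn(zz, th), pr2$radius_fn(zz, th))
})
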