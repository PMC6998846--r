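# Lumen voxelisation, analytic velocity synthesis, phase-contrast
# encoding, and noise.

test_that("lumen mask cross-sections match the analytic circle area", {
  p <- tube_params()
  pr <- build_root_profile(p)
  grid <- list(origin = c(-15.5, -15.5, -9.5), voxel = c(1, 1, 1),
               dims = c(32L, 32L, 40L))
  m <- make_lumen_mask(pr, grid)
  for (k in c(5, 20, 35)) {
    area <- sum(m[, , k])              # voxel area 1 mm^2
    expect_lt(abs(area - pi * 100), 2 * pi * 10 * 1)  # one voxel ring
  }
  # laterally disjoint grid: inside the z range but away from the axis
  far <- list(origin = c(100, 100, 0), voxel = c(1, 1, 1),
              dims = c(8L, 8L, 8L))
  expect_true(!any(make_lumen_mask(pr, far)))
  # axially disjoint grid is an input error
  off <- list(origin = c(0, 0, 500), voxel = c(1, 1, 1),
              dims = c(8L, 8L, 8L))
  expect_error(make_lumen_mask(pr, off), "axial")
})

test_that("sinus slices are wider than the annulus slice", {
  m <- fx_field_small()$mask
  g <- fx_field_small()$grid
  z <- g$origin[3] + (seq_len(g$dims[3]) - 1) * g$voxel[3]
  k_ann <- which.min(abs(z - 0))
  k_sin <- which.min(abs(z - fx_params()$sinus_height / 2))
  expect_gt(sum(m[, , k_sin]), sum(m[, , k_ann]))
})

test_that("steady Poiseuille synthesis reproduces the closed-form centreline", {
  p <- tube_params()
  pr <- build_root_profile(p)
  acq <- acquisition_params(field_of_view = c(24, 24, 40),
                            matrix_size = c(48, 48, 40),
                            z_range = c(-10, 30), n_frames = 2)
  fld <- sample_velocity_field(pr, constant_waveform(31.41593), acq)
  # centreline v_z = 2q/(pi R^2) = 20 cm/s
  ctr <- fld$grid$dims[1:2] / 2
  vz_ctr <- fld$vz[ctr[1], ctr[2], 20, 1]
  expect_equal(vz_ctr, 20, tolerance = 0.01)
  # straight tube: no radial flow anywhere
  expect_lt(max(abs(fld$vx)), 1e-12)
  expect_lt(max(abs(fld$vy)), 1e-12)
  # frames are identical for constant flow
  expect_identical(fld$vz[, , , 1], fld$vz[, , , 2])
})

test_that("zero-flow frames are all zero when the vortex is disabled", {
  acq <- default_acquisition(fx_profile(), matrix_size = c(24, 24, 24),
                             n_frames = 10)
  fld <- sample_velocity_field(fx_profile(), fx_waveform(), acq,
                               vortex = NULL)
  k0 <- which(abs(fld$q_frames) < 1e-12)[1]
  expect_false(is.na(k0))
  expect_identical(max(abs(fld$vx[, , , k0])), 0)
  expect_identical(max(abs(fld$vz[, , , k0])), 0)
})

test_that("velocity vanishes outside the lumen mask before noise", {
  fld <- fx_field_small()
  out <- !fld$mask
  for (k in seq_along(fld$times)) {
    expect_identical(max(abs(fld$vx[, , , k][out])), 0)
    expect_identical(max(abs(fld$vz[, , , k][out])), 0)
  }
})

test_that("discrete divergence of the interior field shrinks under refinement", {
  pr <- fx_profile()
  w <- fx_waveform()
  mx <- function(n, frame) {
    acq <- default_acquisition(pr, matrix_size = c(n, n, n), n_frames = 4)
    fld <- sample_velocity_field(pr, w, acq, vortex = vortex_params())
    field_divergence(fld, pr, frame = frame)$max_abs
  }
  # frame 2 is systolic (jet), frame 4 diastolic (vortex only)
  for (frame in c(2, 4)) {
    coarse <- mx(48, frame); fine <- mx(96, frame)
    expect_lt(fine, 0.6 * coarse)
  }
})

test_that("phase encoding wraps to (-pi, pi] and round-trips below venc", {
  venc <- 100
  v <- seq(-99.9, 99.9, length.out = 1001)
  ph <- valvephantom:::.wrap_phase(pi * v / venc)
  expect_true(all(ph > -pi & ph <= pi))
  expect_equal(pc_decode(ph, venc), v, tolerance = 1e-12)
  # aliasing arithmetic: v beyond venc wraps by multiples of 2*venc
  expect_equal(pc_decode(valvephantom:::.wrap_phase(pi * 150 / venc), venc),
               -50)
  expect_equal(pc_decode(valvephantom:::.wrap_phase(pi * 250 / venc), venc),
               50)
  # documented half-open boundary convention: +/-venc decode to +venc
  expect_equal(pc_decode(valvephantom:::.wrap_phase(pi * 100 / venc), venc),
               100)
  expect_equal(pc_decode(valvephantom:::.wrap_phase(-pi * 100 / venc), venc),
               100)
  # equivariance under v -> v + 2*venc
  expect_equal(pc_decode(valvephantom:::.wrap_phase(pi * (v + 200) / venc),
                         venc), v, tolerance = 1e-9)
})

test_that("field-level encode/decode round trip is exact below venc", {
  fld <- fx_field_small()
  expect_lt(max(abs(fld$vz)), fld$venc)
  rt <- apply_pc_roundtrip(fld)
  expect_equal(rt$vz, fld$vz, tolerance = 1e-12)
  expect_equal(rt$vx, fld$vx, tolerance = 1e-12)
})

test_that("noise is mask-confined, reproducible, and correctly scaled", {
  fld <- fx_field_small()
  expect_identical(add_noise(fld, 0)$vx, fld$vx)
  n1 <- add_noise(fld, 5, seed = 11)
  n2 <- add_noise(fld, 5, seed = 11)
  expect_identical(n1$vx, n2$vx)
  expect_identical(n1$vz, n2$vz)
  out <- !fld$mask
  expect_identical(max(abs(n1$vx[, , , 1][out])), 0)
  resid <- c(n1$vx - fld$vx, n1$vy - fld$vy,
             n1$vz - fld$vz)[rep(fld$mask, 3 * length(fld$times))]
  expect_equal(sd(resid), 5, tolerance = 0.01)
})

test_that("NIfTI export/import round-trips values, grid and metadata", {
  fld <- fx_field_small()
  d <- tempfile()
  export_nifti(fld, d)
  f2 <- import_nifti(d)
  expect_equal(f2$vx, fld$vx)
  expect_equal(f2$vz, fld$vz)
  expect_identical(f2$mask, fld$mask)
  expect_equal(f2$grid$origin, fld$grid$origin)
  expect_equal(f2$grid$voxel, fld$grid$voxel)
  expect_equal(f2$times, fld$times)
  expect_equal(f2$venc, fld$venc)
  expect_equal(f2$vortex_meta$centers, fld$vortex_meta$centers,
               tolerance = 1e-9)
  # mismatched frame counts across components is a format error
  file.copy(file.path(d, "mask.nii.gz"), file.path(d, "vx.nii.gz"),
            overwrite = TRUE)
  expect_error(import_nifti(d), "format error")
})
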