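# RK4 particle tracing oracles: constant advection, solid-body rotation,
# reversibility, termination semantics, vortex capture.

test_that("constant field advects exactly (RK4 is exact for constants)", {
  # uniform v = (10, 0, 0) mm/s = (1, 0, 0) cm/s over a big masked box
  fld <- analytic_tube_field(R = 100, function(X, Y, Z)
    list(vx = X * 0 + 1, vy = X * 0, vz = X * 0),
    dims = c(32, 32, 16), fov = c(64, 64, 32))
  p <- trace_pathlines(fld, rbind(c(0, 0, 0)), t0 = 0, t1 = 1,
                       dt = 0.01)[[1]]
  expect_identical(p$terminated, "none")
  expect_equal(p$positions[nrow(p$positions), ], c(10, 0, 0),
               tolerance = 1e-9)
})

test_that("solid-body rotation conserves radius and orbital period", {
  omega <- 2 * pi            # one turn per second
  fld <- analytic_tube_field(R = 100, function(X, Y, Z)
    list(vx = -omega * Y / 10, vy = omega * X / 10, vz = X * 0),
    dims = c(48, 48, 8), fov = c(48, 48, 8))
  r0 <- 8
  period <- 2 * pi / omega
  p <- trace_pathlines(fld, rbind(c(r0, 0, 0)), t0 = 0, t1 = period,
                       dt = period / 100)[[1]]
  expect_identical(p$terminated, "none")
  radii <- sqrt(rowSums(p$positions[, 1:2]^2))
  expect_lt(max(abs(radii - r0)) / r0, 1e-4)      # O(dt^4) drift
  # measured period from the swept angle
  wn <- pathline_winding(p, c(0, 0, 0), c(0, 0, 1))
  measured_period <- period / wn
  expect_equal(measured_period, period, tolerance = 1e-3)
})

test_that("integrating forward then backward returns to the seed", {
  fld <- analytic_tube_field(R = 100, function(X, Y, Z)
    list(vx = -Y / 10, vy = X / 10, vz = X * 0 + 0.5),
    dims = c(48, 48, 16), fov = c(48, 48, 16))
  seed <- c(6, 2, -3)
  fwd <- trace_pathlines(fld, rbind(seed), t0 = 0, t1 = 1,
                         dt = 0.005)[[1]]
  end <- fwd$positions[nrow(fwd$positions), ]
  neg <- fld
  neg$vx <- -neg$vx; neg$vy <- -neg$vy; neg$vz <- -neg$vz
  back <- trace_pathlines(neg, rbind(end), t0 = 0, t1 = 1,
                          dt = 0.005)[[1]]
  expect_lt(sqrt(sum((back$positions[nrow(back$positions), ] - seed)^2)),
            1e-6)
})

test_that("termination records why and where particles stop", {
  fld <- analytic_tube_field(R = 10, function(X, Y, Z)
    list(vx = X * 0 + 5, vy = X * 0, vz = X * 0),  # 50 mm/s toward +x
    dims = c(32, 32, 8), fov = c(32, 32, 8))
  # seed outside the grid: immediate left_grid, no exception
  p_out <- trace_pathlines(fld, rbind(c(500, 0, 0)), 0, 0.5, 0.01)[[1]]
  expect_identical(p_out$terminated, "left_grid")
  expect_identical(nrow(p_out$positions), 1L)
  # seed inside: advects to the wall and leaves the mask
  p_in <- trace_pathlines(fld, rbind(c(0, 0, 0)), 0, 1, 0.01)[[1]]
  expect_identical(p_in$terminated, "left_mask")
  expect_lt(max(sqrt(rowSums(p_in$positions[, 1:2, drop = FALSE]^2))),
            10 + 1)
})

test_that("diastolic sinus vortex captures particles seeded in the sinus", {
  fld <- fx_field()
  vm <- fld$vortex_meta
  kd <- which(fld$gate == 1)[1]
  t0 <- fld$times[kd]
  seed <- vm$centers[1, ] + c(vm$loop_radius, 0, 0)
  p <- trace_pathlines(fld, rbind(seed), t0 = t0, t1 = t0 + 0.4,
                       dt = fld$period / 400)[[1]]
  wn <- pathline_winding(p, vm$centers[1, ], vm$axes[1, ])
  expect_gte(abs(wn), 1)
})

test_that("pathline writers emit well-formed CSV and VTK", {
  fld <- fx_field_small()
  seeds <- orifice_seeds(fx_profile(), n = 10)
  paths <- trace_pathlines(fld, seeds, t0 = 0, t1 = 0.2,
                           dt = fld$period / 100)
  fc <- tempfile(fileext = ".csv")
  write_pathlines_csv(paths, fc)
  d <- read.csv(fc)
  expect_identical(names(d), c("pathline_id", "t", "x", "y", "z"))
  expect_identical(length(unique(d$pathline_id)), length(paths))
  fv <- tempfile(fileext = ".vtk")
  write_pathlines_vtk(paths, fv)
  lines <- readLines(fv)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  npts <- sum(vapply(paths, function(p) nrow(p$positions), integer(1)))
  expect_identical(lines[5], sprintf("POINTS %d float", npts))
})

test_that("tracing rejects degenerate time arguments", {
  fld <- fx_field_small()
  expect_error(trace_pathlines(fld, rbind(c(0, 0, 0)), 0, 1, dt = -1), "dt")
  expect_error(trace_pathlines(fld, rbind(c(0, 0, 0)), 1, 0.5), "t0 < t1")
})
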