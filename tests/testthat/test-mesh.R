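# Mesh construction, topology and diagnostics.

test_that("root shell is watertight with tube-wall topology", {
  for (m in list(fx_root_mesh_coarse(), fx_root_mesh())) {
    expect_true(is_edge_manifold(m))
    expect_true(is_watertight(m))
    # solid tube wall is a genus-1 closed surface
    expect_identical(euler_characteristic(m), 0L)
    expect_gt(mesh_volume(m), 0)
  }
})

test_that("straight-tube shell volume matches the annular-cylinder closed form", {
  p <- tube_params()
  pr <- build_root_profile(p)
  m <- build_root_mesh(pr, p, n_axial = 30, n_circumferential = 256)
  v_exact <- pi * (12^2 - 10^2) * 50
  expect_equal(mesh_volume(m), v_exact, tolerance = 0.01)
})

test_that("shell volume converges to the closed form as O(1/n^2)", {
  p <- tube_params()
  pr <- build_root_profile(p)
  v_exact <- pi * (12^2 - 10^2) * 50
  err <- vapply(c(32, 64, 128), function(nc) {
    abs(mesh_volume(build_root_mesh(pr, p, n_axial = 12,
                                    n_circumferential = nc)) - v_exact)
  }, numeric(1))
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)
})

test_that("increasing wall thickness strictly increases shell volume", {
  vols <- vapply(c(1.5, 2, 2.5, 3), function(wt) {
    p <- tube_params(wall = wt)
    mesh_volume(build_root_mesh(build_root_profile(p), p, n_axial = 10,
                                n_circumferential = 48))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("root wall thickness measures 2 mm along surface normals", {
  ws <- wall_thickness_stats(fx_root_mesh())
  expect_equal(ws$median, 2.0, tolerance = 0.02)
  expect_equal(ws$mean, 2.0, tolerance = 0.02)
})

test_that("leaflet shell is a closed genus-0 surface at 0.6 mm thickness", {
  leaf <- fx_leaflet()
  expect_true(is_watertight(leaf))
  expect_identical(euler_characteristic(leaf), 2L)
  expect_equal(mesh_min_thickness(leaf), 0.6, tolerance = 0.05)
})

test_that("leaflets are exact rotational images of one another", {
  p <- fx_params()
  l0 <- build_leaflet_mesh(p, 0, profile = fx_profile(), n_u = 24, n_v = 12)
  l1 <- build_leaflet_mesh(p, 1, profile = fx_profile(), n_u = 24, n_v = 12)
  ang <- 2 * pi / 3
  rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
  expect_lt(max(abs(l0$vertices %*% t(rot) - l1$vertices)), 1e-6)
})

test_that("closed free edges of adjacent leaflets coapt at the centreline", {
  p <- fx_params()
  mids <- t(vapply(0:2, function(k) {
    fe <- leaflet_free_edge(p, k, state = "closed", profile = fx_profile(),
                            n = 201)
    fe[101, ]
  }, numeric(3)))
  # mid-curves of finite-thickness shells coapt within ~2 leaflet thicknesses
  for (i in 1:3) {
    d <- sqrt(sum((mids[i, ] - mids[i %% 3 + 1, ])^2))
    expect_lt(d, 2 * p$leaflet_thickness)
  }
})

test_that("fully open valve leaves the annulus orifice unobstructed", {
  p <- fx_params()
  area <- orifice_area(p, open_fraction = 1, profile = fx_profile())
  expect_gte(area, 0.9 * pi * (p$annulus_diameter / 2)^2)
})

test_that("assembled phantom has one wall plus one component per leaflet", {
  m3 <- assemble_phantom(fx_params(), n_axial = 24, n_circumferential = 48,
                         n_u = 16, n_v = 8)
  d3 <- mesh_diagnostics(m3, max_rays = 200)
  expect_true(d3$watertight)
  expect_identical(d3$n_components, 4L)
  expect_setequal(unique(m3$component_labels),
                  c("wall", "leaflet_1", "leaflet_2", "leaflet_3"))
  # wall contributes 0, each genus-0 leaflet contributes 2
  expect_identical(d3$euler_characteristic, 6L)

  p2 <- root_params(n_leaflets = 2)
  m2 <- assemble_phantom(p2, n_axial = 24, n_circumferential = 48,
                         n_u = 16, n_v = 8)
  expect_identical(mesh_diagnostics(m2, max_rays = 200)$n_components, 3L)
})

test_that("assembled phantom is invariant under rotation by 2*pi/n", {
  m <- assemble_phantom(fx_params(), n_axial = 24, n_circumferential = 48,
                        n_u = 16, n_v = 8)
  ang <- 2 * pi / 3
  rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
  vr <- m$vertices %*% t(rot)
  # compare as point sets via rounded coordinate keys
  key <- function(v) sort(paste(round(v[, 1], 5), round(v[, 2], 5),
                                round(v[, 3], 5)))
  expect_identical(key(vr), key(m$vertices))
})

test_that("diagnostics flag reference solids correctly", {
  s <- icosphere(3)
  d <- mesh_diagnostics(s, max_rays = 300)
  expect_true(d$watertight)
  expect_identical(d$euler_characteristic, 2L)
  expect_equal(d$volume_mm3, 4 * pi / 3, tolerance = 0.01)
  expect_equal(d$min_thickness_mm, 2, tolerance = 0.01)  # diameter

  expect_false(is_watertight(open_cube()))
  expect_error(mesh_diagnostics(surface_mesh(matrix(0, 0, 3),
                                             matrix(0L, 0, 3))), "empty")
})

test_that("incompatible leaflet and root parameters raise geometry errors", {
  expect_error(build_leaflet_mesh(root_params(leaflet_height = 25)),
               "sinus segment")
  expect_error(build_leaflet_mesh(root_params(coaptation_height = 13.9,
                                              leaflet_height = 13)),
               "coaptation_height")
  expect_error(build_leaflet_mesh(fx_params(), leaflet_index = 3),
               "leaflet_index")
})
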