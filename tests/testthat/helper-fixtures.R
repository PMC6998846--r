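# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)
  .fx[[name]]
}

fx_params <- function() root_params()

fx_profile <- function() fx("profile", build_root_profile(fx_params()))

# default-resolution meshes (the printable phantom)
fx_root_mesh <- function() fx("root_mesh",
  build_root_mesh(fx_profile(), fx_params()))

fx_leaflet <- function() fx("leaflet",
  build_leaflet_mesh(fx_params(), profile = fx_profile()))

# coarse meshes for topology-only checks
fx_root_mesh_coarse <- function() fx("root_mesh_coarse",
  build_root_mesh(fx_profile(), fx_params(), n_axial = 24,
                  n_circumferential = 48))

fx_waveform <- function() fx("waveform", default_aortic_waveform())

# straight-tube parameter set (degenerate geometry, 10 mm inner radius,
# 50 mm total length)
tube_params <- function(wall = 2) {
  root_params(annulus_diameter = 20, sinus_max_diameter = 20,
              sinus_height = 20, sinotubular_diameter = 20,
              ascending_aorta_diameter = 20, ascending_aorta_length = 20,
              lvot_diameter = 20, lvot_length = 10, wall_thickness = wall)
}

# a steady flow_waveform with constant flow (mL/s), for analytic fields
constant_waveform <- function(q0, period = 1, n = 100) {
  structure(list(times = seq(0, period, length.out = n + 1)[seq_len(n)],
                 q = rep(q0, n), period = period,
                 q_fun = function(t) rep(q0, length(t)),
                 t_peak = period / 2, params = NULL),
            class = "flow_waveform")
}

# hand-built steady velocity field (cm/s) on a cylinder mask of radius R:
# velocity given by vfun(X, Y, Z) returning list(vx, vy, vz) in cm/s
analytic_tube_field <- function(R = 10, vfun, dims = c(48, 48, 24),
                                fov = c(24, 24, 24), n_frames = 2,
                                venc = 100) {
  grid <- list(origin = -fov / 2 + fov / dims / 2, voxel = fov / dims,
               dims = as.integer(dims))
  ax <- list(x = grid$origin[1] + (seq_len(dims[1]) - 1) * grid$voxel[1],
             y = grid$origin[2] + (seq_len(dims[2]) - 1) * grid$voxel[2],
             z = grid$origin[3] + (seq_len(dims[3]) - 1) * grid$voxel[3])
  X <- array(ax$x, dims)
  Y <- array(rep(ax$y, each = dims[1]), dims)
  Z <- array(rep(ax$z, each = dims[1] * dims[2]), dims)
  mask <- sqrt(X^2 + Y^2) < R
  v <- vfun(X, Y, Z)
  zero <- function(a) { a[!mask] <- 0; a }
  rep4 <- function(a) array(rep(zero(a), n_frames), c(dims, n_frames))
  velocity_field(rep4(v$vx), rep4(v$vy), rep4(v$vz), mask, grid,
                 times = (seq_len(n_frames) - 0.5) / n_frames,
                 period = 1, venc = venc)
}

# default noise-free synthetic dataset (64^3, 20 frames, with vortex)
fx_field <- function() fx("field", {
  acq <- default_acquisition(fx_profile())
  sample_velocity_field(fx_profile(), fx_waveform(), acq,
                        vortex = vortex_params())
})

# small dataset for cheap tests
fx_field_small <- function() fx("field_small", {
  acq <- default_acquisition(fx_profile(), matrix_size = c(32, 32, 32),
                             n_frames = 8)
  sample_velocity_field(fx_profile(), fx_waveform(), acq,
                        vortex = vortex_params())
})

# open cube (one face removed) for watertightness failure checks
open_cube <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7))   # x = 0 (x = 1 face removed)
  surface_mesh(v, f)
}
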