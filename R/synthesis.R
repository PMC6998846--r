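# Synthetic time-resolved phase-contrast velocity data over the phantom
# lumen. The axial flow is a parabolic (or plug) profile over the core
# radius R(z) carrying exactly the programmed flux q(t) through every
# plane; the radial component is the exact solution of continuity, so the
# analytic field is divergence-free. An optional solenoidal vortex term
# (curl of a Gaussian vector potential, one vortex per sinus) is gated on
# during diastole. Velocities are stored in cm/s, positions in mm.

#' Sinus vortex model parameters
#'
#' One Gaussian-core vortex per sinus of Valsalva, built as the curl of a
#' vector potential aligned with the local circumferential direction, so
#' the swirl lies in the radial-axial plane of each sinus (the vortex ring
#' plane). The field is solenoidal by construction. The vortex is gated on
#' smoothly when the instantaneous pump flow falls below a fraction of the
#' peak (diastole).
#'
#' @param strength Circulation of each vortex, cm^2/s, measured on the
#'   reference loop of radius `sqrt(2) * core_radius` around the core.
#' @param core_radius Gaussian core scale sigma, mm.
#' @param center_height_frac Vortex centre height as a fraction of
#'   `sinus_height`.
#' @param gate_low,gate_high Smoothstep gate bounds as fractions of peak
#'   flow: the vortex is fully on below `gate_low * peak` and fully off
#'   above `gate_high * peak`.
#' @return A `vortex_params` object.
#' @export
vortex_params <- function(strength = 50, core_radius = 2.5,
                          center_height_frac = 0.5, gate_low = 0.05,
                          gate_high = 0.15) {
  if (core_radius <= 0) stop("core_radius must be > 0", call. = FALSE)
  if (gate_low < 0 || gate_high <= gate_low)
    stop("need 0 <= gate_low < gate_high", call. = FALSE)
  structure(list(strength = strength, core_radius = core_radius,
                 center_height_frac = center_height_frac,
                 gate_low = gate_low, gate_high = gate_high),
            class = "vortex_params")
}

# vortex centres and axes for each sinus; returns list of (center, axis)
.vortex_geometry <- function(profile, vp) {
  n <- profile$n_fold
  zc <- vp$center_height_frac * profile$params$sinus_height
  rc <- profile$r_base(zc)
  lapply(seq_len(n) - 1L, function(k) {
    th <- 2 * pi * k / n      # sinus bulge peaks are at theta = 2*pi*k/n
    list(center = c(rc * cos(th), rc * sin(th), zc),
         axis = c(-sin(th), cos(th), 0),
         radial = c(cos(th), sin(th), 0))
  })
}

# static vortex velocity field (cm/s) for unit gate at the given points
# (n x 3 mm). Circulation on the reference loop equals vp$strength.
.vortex_velocity <- function(pts, profile, vp) {
  sig <- vp$core_radius
  a_ref <- sqrt(2) * sig
  # circulation(a) = 2*pi*(a/10) * C * (a/sig^2) * exp(-a^2/(2 sig^2)) [cm^2/s]
  C <- vp$strength / (2 * pi * (a_ref / 10) * (a_ref / sig^2) *
                        exp(-a_ref^2 / (2 * sig^2)))
  v <- matrix(0, nrow(pts), 3)
  for (g in .vortex_geometry(profile, vp)) {
    s <- sweep(pts, 2, g$center)
    d2 <- rowSums(s^2)
    # v = grad(g) x axis, grad(g) = -C/sig^2 * exp(-d^2/2sig^2) * s
    coef <- -C / sig^2 * exp(-d2 / (2 * sig^2))
    gx <- coef * s[, 1]; gy <- coef * s[, 2]; gz <- coef * s[, 3]
    ax <- g$axis
    v <- v + cbind(gy * ax[3] - gz * ax[2],
                   gz * ax[1] - gx * ax[3],
                   gx * ax[2] - gy * ax[1])
  }
  v
}

# diastolic gate (1 = vortex on) as a function of instantaneous flow
.vortex_gate <- function(q, peak, vp) {
  x <- (q / peak - vp$gate_low) / (vp$gate_high - vp$gate_low)
  1 - .smoothstep(x)
}

#' Voxelise the phantom lumen
#'
#' Marks voxel centres whose radial distance from the flow axis is below
#' the lumen radius `radius_fn(z, theta)` of the profile.
#'
#' @param profile A [build_root_profile()] result.
#' @param grid A grid (the `grid` element of [acquisition_params()]).
#' @return A logical array of dimension `grid$dims`.
#' @export
make_lumen_mask <- function(profile, grid) {
  ax <- .grid_axes(grid)
  if (max(ax$z) < profile$z_min || min(ax$z) > profile$z_max)
    stop("grid does not intersect the profile's axial extent", call. = FALSE)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  X <- array(ax$x, c(nx, ny, nz))
  Y <- array(rep(ax$y, each = nx), c(nx, ny, nz))
  Z <- array(rep(ax$z, each = nx * ny), c(nx, ny, nz))
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  R <- array(profile$radius_fn(as.vector(Z), as.vector(th)), c(nx, ny, nz))
  inz <- Z >= profile$z_min & Z <= profile$z_max
  r < R & inz
}

#' Construct a velocity field object directly
#'
#' Low-level constructor for time-resolved three-component velocity data on
#' a regular grid (used by [sample_velocity_field()] and by tests that need
#' analytic fields).
#'
#' @param vx,vy,vz 4D arrays `[nx, ny, nz, n_frames]`, cm/s.
#' @param mask Logical 3D lumen mask.
#' @param grid Grid description (`origin`, `voxel`, `dims`).
#' @param times Frame-centre times, s (one cycle).
#' @param period Cycle period, s.
#' @param venc Velocity encoding, cm/s.
#' @param vortex_meta Optional list describing the embedded vortex model.
#' @return A `velocity_field` object.
#' @export
velocity_field <- function(vx, vy, vz, mask, grid, times, period, venc,
                           vortex_meta = NULL) {
  dims <- dim(vx)
  stopifnot(length(dims) == 4, all(dim(vy) == dims), all(dim(vz) == dims),
            all(dim(mask) == dims[1:3]), length(times) == dims[4])
  structure(list(vx = vx, vy = vy, vz = vz, mask = mask, grid = grid,
                 times = times, period = period, venc = venc,
                 vortex_meta = vortex_meta),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d x %d voxels, %d frames, venc %g cm/s\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              length(x$times), x$venc))
  cat(sprintf("  lumen voxels: %d (%.1f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Synthesise the time-resolved velocity field over the phantom lumen
#'
#' Builds the noise-free analytic flow field sampled at voxel centres and
#' frame centres: an axial profile over the core radius `R(z)` (the
#' theta-minimum lumen radius) carrying exactly the waveform flux `q(t)`
#' through every axial plane,
#' \deqn{v_z(r,z,t) = \frac{2 q(t)}{\pi R(z)^2}\left(1 - \frac{r^2}{R(z)^2}\right)}
#' for the parabolic profile, with the radial component
#' \deqn{v_r = \frac{2 q}{\pi R^2} R'(z) \frac{r}{R}\left(1 - \frac{r^2}{R^2}\right)}
#' given by exact continuity (the plug profile uses the analogous pair).
#' An optional diastole-gated sinus vortex term (see [vortex_params()]) is
#' added as the curl of a vector potential, so the combined analytic field
#' remains divergence-free. Velocity is zero outside the lumen mask.
#'
#' @param profile A [build_root_profile()] result.
#' @param w A `flow_waveform` from [make_aortic_waveform()].
#' @param acq An [acquisition_params()] object.
#' @param vortex A [vortex_params()] object, or `NULL` for no vortex.
#' @param profile_shape `"parabolic"` (default) or `"plug"`.
#' @return A [velocity_field()] object (cm/s).
#' @export
sample_velocity_field <- function(profile, w, acq, vortex = NULL,
                                  profile_shape = c("parabolic", "plug")) {
  profile_shape <- match.arg(profile_shape)
  grid <- acq$grid
  nf <- acq$n_frames
  mask <- make_lumen_mask(profile, grid)
  ax <- .grid_axes(grid)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]

  idx <- which(mask)
  X <- array(ax$x, c(nx, ny, nz))[idx]
  Y <- array(rep(ax$y, each = nx), c(nx, ny, nz))[idx]
  Z <- array(rep(ax$z, each = nx * ny), c(nx, ny, nz))[idx]
  r <- sqrt(X^2 + Y^2)
  R <- profile$r_base(Z)
  dR <- .rbase_dz(profile, Z)
  core <- r < R

  # unit-flux profile (velocity cm/s for q = 1 mL/s = 1000 mm^3/s)
  uz <- numeric(length(idx)); ur <- numeric(length(idx))
  if (profile_shape == "parabolic") {
    s2 <- (r[core] / R[core])^2
    uz[core] <- 200 / (pi * R[core]^2) * (1 - s2)
    ur[core] <- 200 / (pi * R[core]^2) * dR[core] * (r[core] / R[core]) *
      (1 - s2)
  } else {
    uz[core] <- 100 / (pi * R[core]^2)
    ur[core] <- 100 * r[core] * dR[core] / (pi * R[core]^3)
  }
  cth <- ifelse(r > 0, X / r, 0); sth <- ifelse(r > 0, Y / r, 0)
  ux <- ur * cth; uy <- ur * sth

  wx <- wy <- wz <- NULL
  vortex_meta <- NULL
  if (!is.null(vortex)) {
    vv <- .vortex_velocity(cbind(X, Y, Z), profile, vortex)
    wx <- vv[, 1]; wy <- vv[, 2]; wz <- vv[, 3]
    geom <- .vortex_geometry(profile, vortex)
    vortex_meta <- list(params = unclass(vortex),
                        centers = do.call(rbind, lapply(geom, `[[`, "center")),
                        axes = do.call(rbind, lapply(geom, `[[`, "axis")),
                        radials = do.call(rbind, lapply(geom, `[[`, "radial")),
                        loop_radius = sqrt(2) * vortex$core_radius)
  }

  times <- (seq_len(nf) - 0.5) / nf * w$period
  qf <- if (!is.null(w$q_fun)) w$q_fun(times)
    else stats::approx(c(w$times, w$period), c(w$q, w$q[1]),
                       xout = times %% w$period)$y
  pk <- peak_flow(w)
  gate <- if (is.null(vortex)) numeric(nf)
    else .vortex_gate(qf, pk, vortex)

  vx <- array(0, c(nx, ny, nz, nf))
  vy <- array(0, c(nx, ny, nz, nf))
  vz <- array(0, c(nx, ny, nz, nf))
  nvox <- as.integer(nx) * ny * nz
  for (k in seq_len(nf)) {
    off <- (k - 1) * nvox
    fx <- qf[k] * ux; fy <- qf[k] * uy; fz <- qf[k] * uz
    if (!is.null(wx) && gate[k] > 0) {
      fx <- fx + gate[k] * wx
      fy <- fy + gate[k] * wy
      fz <- fz + gate[k] * wz
    }
    vx[off + idx] <- fx
    vy[off + idx] <- fy
    vz[off + idx] <- fz
  }
  fld <- velocity_field(vx, vy, vz, mask, grid, times, w$period, acq$venc,
                        vortex_meta = vortex_meta)
  fld$q_frames <- qf
  fld$gate <- gate
  fld
}

# ---- phase-contrast encoding --------------------------------------------

# wrap phase to (-pi, pi]
.wrap_phase <- function(phi) {
  phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
}

#' Phase-contrast velocity encoding and decoding
#'
#' `pc_encode()` maps each velocity component to a phase
#' `wrap(pi * v / venc)` in the half-open interval `(-pi, pi]`;
#' `pc_decode()` maps phase back to velocity `phase * venc / pi`. The round
#' trip is the identity for `|v| < venc`; velocities at or beyond the venc
#' alias by multiples of `2 * venc` (exactly `+venc` maps to `+venc`,
#' exactly `-venc` aliases to `+venc` under the half-open convention).
#'
#' @param field A [velocity_field()].
#' @return `pc_encode()`: a list with `phase_x`, `phase_y`, `phase_z`
#'   arrays (radians) and `venc`; `pc_decode()`: the velocity array(s).
#' @export
pc_encode <- function(field) {
  v2p <- function(v) .wrap_phase(pi * v / field$venc)
  list(phase_x = v2p(field$vx), phase_y = v2p(field$vy),
       phase_z = v2p(field$vz), venc = field$venc)
}

#' @rdname pc_encode
#' @param phase A phase array (radians), or the list returned by
#'   [pc_encode()].
#' @param venc Velocity-encoding limit, cm/s.
#' @export
pc_decode <- function(phase, venc) {
  if (is.list(phase)) {
    venc <- phase$venc
    return(list(vx = phase$phase_x * venc / pi,
                vy = phase$phase_y * venc / pi,
                vz = phase$phase_z * venc / pi))
  }
  phase * venc / pi
}

#' Encode-decode round trip of a velocity field
#'
#' Applies [pc_encode()] then [pc_decode()] in place: the identity for
#' velocities below the venc, and the standard aliasing by `2 * venc`
#' beyond it. Useful for demonstrating and testing aliasing bias in flow
#' quantification.
#'
#' @param field A [velocity_field()].
#' @return The round-tripped `velocity_field`.
#' @export
apply_pc_roundtrip <- function(field) {
  d <- pc_decode(pc_encode(field))
  field$vx <- d$vx; field$vy <- d$vy; field$vz <- d$vz
  field
}

#' Add measurement noise to a velocity field
#'
#' Adds independent Gaussian noise (SD `noise_sd`, cm/s) to every velocity
#' component of every voxel inside the lumen mask, in every frame.
#' Reproducible under a fixed seed; the caller's RNG state is preserved.
#'
#' @param field A [velocity_field()].
#' @param noise_sd Noise standard deviation, cm/s.
#' @param seed Integer seed.
#' @return The noisy `velocity_field`.
#' @export
add_noise <- function(field, noise_sd, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(field)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  nf <- length(field$times)
  nvox <- prod(field$grid$dims)
  midx <- which(field$mask)
  for (k in seq_len(nf)) {
    off <- (k - 1) * nvox
    field$vx[off + midx] <- field$vx[off + midx] +
      stats::rnorm(length(midx), sd = noise_sd)
    field$vy[off + midx] <- field$vy[off + midx] +
      stats::rnorm(length(midx), sd = noise_sd)
    field$vz[off + midx] <- field$vz[off + midx] +
      stats::rnorm(length(midx), sd = noise_sd)
  }
  field$noise_sd <- noise_sd
  field
}

# binary erosion of a logical volume by one 6-connected step
.erode_mask <- function(m, steps = 1) {
  d <- dim(m)
  for (s in seq_len(steps)) {
    out <- m
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
    for (sh in shifts) {
      ix <- pmin(pmax(seq_len(d[1]) + sh[1], 1), d[1])
      iy <- pmin(pmax(seq_len(d[2]) + sh[2], 1), d[2])
      iz <- pmin(pmax(seq_len(d[3]) + sh[3], 1), d[3])
      out <- out & m[ix, iy, iz]
    }
    m <- out
  }
  m
}

#' Discrete divergence of a velocity frame
#'
#' Central-difference divergence (1/s) of one frame, with the interior
#' region over which the solenoidality of the synthetic field can be
#' checked: lumen voxels eroded by `erode` steps (so no stencil crosses
#' the wall) and, when the field carries a jet, excluding a band of
#' `erode` voxels around the jet edge r = R(z), where the finite-support
#' profile has its idealised shear layer (a gradient discontinuity).
#' On the remaining interior the analytic field is smooth and
#' divergence-free, so the discrete norm decreases as O(h^2).
#'
#' @param field A [velocity_field()] from [sample_velocity_field()].
#' @param profile The [build_root_profile()] the field was synthesised
#'   from (used to locate the jet edge); `NULL` skips the jet-edge band.
#' @param frame Frame index.
#' @param erode Erosion steps (default 2).
#' @return List with `divergence` (3D array, NA outside the interior) and
#'   `interior` (logical array), plus `max_abs`.
#' @export
field_divergence <- function(field, profile = NULL, frame = 1, erode = 2) {
  g <- field$grid
  d <- g$dims
  nvox <- prod(d)
  off <- (frame - 1) * nvox
  fa <- function(a) array(a[off + seq_len(nvox)], d) * 10   # cm/s -> mm/s
  vx <- fa(field$vx); vy <- fa(field$vy); vz <- fa(field$vz)
  div <- array(NA_real_, d)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  div[i, j, k] <-
    (vx[i + 1, j, k] - vx[i - 1, j, k]) / (2 * g$voxel[1]) +
    (vy[i, j + 1, k] - vy[i, j - 1, k]) / (2 * g$voxel[2]) +
    (vz[i, j, k + 1] - vz[i, j, k - 1]) / (2 * g$voxel[3])
  interior <- .erode_mask(field$mask, erode)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  if (!is.null(profile)) {
    ax <- .grid_axes(g)
    X <- array(ax$x, d)
    Y <- array(rep(ax$y, each = d[1]), d)
    Z <- array(rep(ax$z, each = d[1] * d[2]), d)
    r <- sqrt(X^2 + Y^2)
    R <- array(profile$r_base(as.vector(Z)), d)
    band <- erode * max(g$voxel)
    interior <- interior & abs(r - R) > band
  }
  list(divergence = div, interior = interior,
       max_abs = max(abs(div[interior]), na.rm = TRUE))
}
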