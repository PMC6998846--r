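# Particle pathlines through the time-resolved velocity field: classical
# RK4 on dx/dt = v(x, t), trilinear in space and linear in time between
# frame centres with periodic extension. Particles terminate on leaving
# the lumen mask or the grid.

# velocity (mm/s) at points (n x 3) and scalar time t, for the active rows
.field_velocity <- function(field, pts, t) {
  nf <- length(field$times)
  nvox <- prod(field$grid$dims)
  # fractional frame position (frame centres at (k - 0.5)/nf * period)
  frac <- (t / field$period) %% 1
  fpos <- frac * nf + 0.5
  k0 <- floor(fpos)
  wt <- fpos - k0
  k0 <- ((k0 - 1) %% nf) + 1
  k1 <- (k0 %% nf) + 1
  comp <- function(a) {
    o0 <- (k0 - 1) * nvox; o1 <- (k1 - 1) * nvox
    v0 <- .interp3(a[o0 + seq_len(nvox)], field$grid, pts)
    v1 <- .interp3(a[o1 + seq_len(nvox)], field$grid, pts)
    (1 - wt) * v0 + wt * v1
  }
  vx <- comp(field$vx); vy <- comp(field$vy); vz <- comp(field$vz)
  out <- cbind(vx, vy, vz) * 10    # cm/s -> mm/s
  attr(out, "inside") <- attr(vx, "inside")
  out
}

#' Trace particle pathlines
#'
#' Integrates massless particles through the velocity field with classical
#' fourth-order Runge-Kutta, trilinear interpolation in space and linear
#' interpolation in time between frame centres (periodic over the cycle).
#' A particle terminates when it leaves the lumen mask (`"left_mask"`) or
#' the grid (`"left_grid"`); a seed outside the grid at `t0` terminates
#' immediately rather than raising an error.
#'
#' @param field A [velocity_field()].
#' @param seeds n x 3 matrix of seed points, mm.
#' @param t0,t1 Start and end times, s (`t0 < t1`).
#' @param dt Time step, s (default period/200).
#' @return A list of `pathline` objects, each with `seed`, `times`,
#'   `positions` (m x 3), and `terminated` (`"none"`, `"left_mask"` or
#'   `"left_grid"`).
#' @export
trace_pathlines <- function(field, seeds, t0 = 0, t1 = field$period,
                            dt = field$period / 200) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t0 >= t1) stop("need t0 < t1", call. = FALSE)
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  ns <- nrow(seeds)
  nsteps <- ceiling((t1 - t0) / dt - 1e-9)
  tgrid <- t0 + dt * (0:nsteps)
  tgrid[length(tgrid)] <- t1

  pos <- array(NA_real_, c(nsteps + 1, ns, 3))
  pos[1, , ] <- seeds
  status <- rep("none", ns)
  last <- rep(1L, ns)       # index of last recorded position
  active <- rep(TRUE, ns)

  # seeds outside the grid or lumen terminate immediately
  m0 <- .interp3(as.numeric(field$mask), field$grid, seeds)
  ingrid <- attr(m0, "inside")
  status[!ingrid] <- "left_grid"
  status[ingrid & m0 < 0.5] <- "left_mask"
  active <- status == "none"

  for (s in seq_len(nsteps)) {
    if (!any(active)) break
    h <- tgrid[s + 1] - tgrid[s]
    x <- matrix(pos[s, active, ], ncol = 3)
    t <- tgrid[s]
    k1 <- .field_velocity(field, x, t)
    k2 <- .field_velocity(field, x + h / 2 * k1, t + h / 2)
    k3 <- .field_velocity(field, x + h / 2 * k2, t + h / 2)
    k4 <- .field_velocity(field, x + h * k3, t + h)
    xn <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

    m <- .interp3(as.numeric(field$mask), field$grid, xn)
    ok_grid <- attr(m, "inside")
    ok_mask <- ok_grid & m >= 0.5
    ai <- which(active)
    status[ai[!ok_grid]] <- "left_grid"
    status[ai[ok_grid & m < 0.5]] <- "left_mask"
    keep <- ok_mask
    if (any(keep)) {
      pos[s + 1, ai[keep], ] <- xn[keep, , drop = FALSE]
      last[ai[keep]] <- s + 1L
    }
    active[ai[!keep]] <- FALSE
  }

  lapply(seq_len(ns), function(i) {
    m <- last[i]
    structure(list(seed = seeds[i, ],
                   times = tgrid[seq_len(m)],
                   positions = matrix(pos[seq_len(m), i, ], ncol = 3),
                   terminated = status[i]),
              class = "pathline")
  })
}

#' @export
print.pathline <- function(x, ...) {
  cat(sprintf("pathline: %d points over [%.3f, %.3f] s, terminated: %s\n",
              nrow(x$positions), x$times[1], x$times[length(x$times)],
              x$terminated))
  invisible(x)
}

#' Seeds at the valve orifice
#'
#' A disk of seed points just above the annulus plane (default z = 1 mm),
#' spread on concentric rings inside the annulus radius.
#'
#' @param profile A [build_root_profile()] result.
#' @param n Approximate number of seeds.
#' @param z Axial position, mm.
#' @param radius_fraction Fraction of the annulus radius covered.
#' @return An n x 3 matrix of seed points.
#' @export
orifice_seeds <- function(profile, n = 50, z = 1,
                          radius_fraction = 0.8) {
  rmax <- profile$radius_fn(0, 0) * radius_fraction
  nr <- max(1, round(sqrt(n / pi)))
  pts <- c(0, 0, z)
  for (ir in seq_len(nr)) {
    r <- rmax * ir / nr
    nth <- max(1, round(2 * pi * ir))
    th <- seq(0, 2 * pi, length.out = nth + 1)[seq_len(nth)]
    pts <- rbind(pts, cbind(r * cos(th), r * sin(th), z))
  }
  unname(as.matrix(pts))
}

#' Winding number of a pathline about an axis
#'
#' Total signed angle (in turns) swept by the particle around `center` in
#' the plane perpendicular to `axis` — used to detect vortex capture.
#'
#' @param path A `pathline`.
#' @param center Rotation centre, mm.
#' @param axis Rotation axis (unit vector not required).
#' @return Signed number of turns.
#' @export
pathline_winding <- function(path, center, axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- c(ref[2] * axis[3] - ref[3] * axis[2],
          ref[3] * axis[1] - ref[1] * axis[3],
          ref[1] * axis[2] - ref[2] * axis[1])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(axis[2] * u1[3] - axis[3] * u1[2],
          axis[3] * u1[1] - axis[1] * u1[3],
          axis[1] * u1[2] - axis[2] * u1[1])
  rel <- sweep(path$positions, 2, center)
  a <- rel %*% u1
  b <- rel %*% u2
  ang <- atan2(b, a)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi   # unwrap increments
  sum(d) / (2 * pi)
}

#' Write pathlines to CSV or VTK
#'
#' CSV columns: `pathline_id`, `t`, `x`, `y`, `z`. The VTK writer emits a
#' legacy ASCII polydata file with one polyline per pathline.
#'
#' @param paths List of `pathline` objects from [trace_pathlines()].
#' @param path Output file path.
#' @export
write_pathlines_csv <- function(paths, path) {
  d <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(pathline_id = i, t = p$times, x = p$positions[, 1],
               y = p$positions[, 2], z = p$positions[, 3])
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathlines_csv
#' @export
write_pathlines_vtk <- function(paths, path) {
  npts <- sum(vapply(paths, function(p) nrow(p$positions), integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "valvephantom pathlines",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", npts)), con)
  for (p in paths)
    writeLines(sprintf("%.6f %.6f %.6f", p$positions[, 1],
                       p$positions[, 2], p$positions[, 3]), con)
  sizes <- vapply(paths, function(p) nrow(p$positions), integer(1))
  writeLines(sprintf("LINES %d %d", length(paths),
                     length(paths) + npts), con)
  off <- 0
  for (i in seq_along(paths)) {
    ids <- off + seq_len(sizes[i]) - 1
    writeLines(paste(c(sizes[i], ids), collapse = " "), con)
    off <- off + sizes[i]
  }
  invisible(path)
}
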