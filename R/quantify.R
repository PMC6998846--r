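# Flow quantification on a velocity_field: through-plane flow waveforms,
# net (cycle-mean) and peak flow, forward/backward volumes and regurgitant
# fraction, proximal-distal conservation, and sinus vortex circulation.

#' Specify a flow-measurement plane
#'
#' A square sampling window centred at `origin` with half-size `extent`,
#' oriented by the unit `normal`, sampled on a regular lattice of pitch
#' `sampling_step`. Sample points falling outside the lumen (interpolated
#' mask < 0.5) are excluded.
#'
#' @param origin Plane centre, mm (length-3).
#' @param normal Plane normal (normalised internally).
#' @param extent Half-size of the square window, mm.
#' @param sampling_step Lattice pitch, mm (default 0.2).
#' @return A `plane_spec` object (with precomputed in-plane basis).
#' @export
plane_spec <- function(origin, normal = c(0, 0, 1), extent = 20,
                       sampling_step = 0.2) {
  if (extent <= 0 || sampling_step <= 0)
    stop("extent and sampling_step must be > 0", call. = FALSE)
  n <- normal / sqrt(sum(normal^2))
  if (!all(is.finite(n))) stop("normal must be a nonzero vector",
                               call. = FALSE)
  # in-plane orthonormal basis
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ref[2] * n[3] - ref[3] * n[2],
         ref[3] * n[1] - ref[1] * n[3],
         ref[1] * n[2] - ref[2] * n[1])
  u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  structure(list(origin = origin, normal = n, extent = extent,
                 sampling_step = sampling_step, u = u, w = w),
            class = "plane_spec")
}

# lattice of sample points on the plane: list(pts = n x 3, dA = mm^2)
.plane_points <- function(plane) {
  s <- seq(-plane$extent, plane$extent, by = plane$sampling_step)
  g <- expand.grid(a = s, b = s)
  pts <- outer(g$a, plane$u) + outer(g$b, plane$w)
  pts <- sweep(pts, 2, plane$origin, "+")
  list(pts = pts, dA = plane$sampling_step^2)
}

# mask-weighted through-plane flow at one frame given precomputed points
.plane_flow_at <- function(field, plane, pp, frame) {
  nvox <- prod(field$grid$dims)
  off <- (frame - 1) * nvox
  g1 <- field$grid
  m <- .interp3(as.numeric(field$mask), g1, pp$pts)
  keep <- m >= 0.5
  if (!any(keep)) return(0)
  pts <- pp$pts[keep, , drop = FALSE]
  frame_arr <- function(a) a[off + seq_len(nvox)]
  vx <- .interp3(frame_arr(field$vx), g1, pts)
  vy <- .interp3(frame_arr(field$vy), g1, pts)
  vz <- .interp3(frame_arr(field$vz), g1, pts)
  vn_cm <- vx * plane$normal[1] + vy * plane$normal[2] + vz * plane$normal[3]
  # cm/s * mm^2 -> mL/s: 1 cm/s = 10 mm/s; 1 mL = 1000 mm^3
  sum(vn_cm * 10 * pp$dA) / 1000
}

#' Through-plane flow at one frame
#'
#' Surface integral `Q = sum (v . n) dA` over the plane sample points
#' inside the lumen, with trilinear velocity interpolation. Units: mL/s.
#'
#' @param field A [velocity_field()].
#' @param plane A [plane_spec()].
#' @param frame Frame index (1-based).
#' @return Flow in mL/s.
#' @export
plane_flow <- function(field, plane, frame = 1) {
  if (frame < 1 || frame > length(field$times))
    stop("frame out of range", call. = FALSE)
  pp <- .plane_points(plane)
  inside <- attr(.interp3(as.numeric(field$mask), field$grid, pp$pts),
                 "inside")
  if (!any(inside))
    stop("plane does not intersect the grid", call. = FALSE)
  .plane_flow_at(field, plane, pp, frame)
}

#' Quantify the flow waveform through a plane
#'
#' Computes the per-frame through-plane flow and the scalar metrics the
#' 4D-flow analysis reports: net (cycle-mean) flow by trapezoidal
#' quadrature with periodic closure, peak flow (maximum over frames),
#' forward and backward volumes by sign-split integration, and the
#' regurgitant fraction (backward / forward volume; 0 when there is no
#' forward volume).
#'
#' @param field A [velocity_field()].
#' @param plane A [plane_spec()].
#' @return A `flow_result` object with `times`, `q`, `net_flow`,
#'   `peak_flow` (mL/s), `forward_volume`, `backward_volume` (mL) and
#'   `regurgitant_fraction`.
#' @export
quantify_plane <- function(field, plane) {
  nf <- length(field$times)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  pp <- .plane_points(plane)
  inside <- attr(.interp3(as.numeric(field$mask), field$grid, pp$pts),
                 "inside")
  if (!any(inside))
    stop("plane does not intersect the grid", call. = FALSE)
  q <- vapply(seq_len(nf), function(k) .plane_flow_at(field, plane, pp, k),
              numeric(1))
  # periodic trapezoid over frame centres
  tt <- c(field$times, field$times[1] + field$period)
  qq <- c(q, q[1])
  dt <- diff(tt)
  net <- sum(dt * (qq[-1] + qq[-length(qq)]) / 2) / field$period
  fwd <- sum(dt * (pmax(qq[-1], 0) + pmax(qq[-length(qq)], 0)) / 2)
  bwd <- sum(dt * (pmax(-qq[-1], 0) + pmax(-qq[-length(qq)], 0)) / 2)
  structure(list(times = field$times, q = q, net_flow = net,
                 peak_flow = max(q), forward_volume = fwd,
                 backward_volume = bwd,
                 regurgitant_fraction = if (fwd > 0) bwd / fwd else 0,
                 plane = plane),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf(paste0("flow_result: net %.3f mL/s, peak %.2f mL/s, ",
                     "forward %.3f mL, backward %.3f mL, RF %.4f\n"),
              x$net_flow, x$peak_flow, x$forward_volume, x$backward_volume,
              x$regurgitant_fraction))
  invisible(x)
}

#' Proximal-distal flow conservation check
#'
#' Quantifies net flow through two planes and reports the relative
#' difference `|net_a - net_b| / max(|net_a|, |net_b|)` — the software
#' analogue of comparing measurements proximal and distal to the valve.
#'
#' @param field A [velocity_field()].
#' @param plane_proximal,plane_distal [plane_spec()] objects.
#' @return List with `net_a`, `net_b` (mL/s) and `relative_difference`.
#' @export
conservation_check <- function(field, plane_proximal, plane_distal) {
  a <- quantify_plane(field, plane_proximal)$net_flow
  b <- quantify_plane(field, plane_distal)$net_flow
  denom <- max(abs(a), abs(b))
  list(net_a = a, net_b = b,
       relative_difference = if (denom > 0) abs(a - b) / denom else 0)
}

#' Default measurement planes relative to the annulus
#'
#' Transverse planes 10 mm proximal (z = -10) and 30 mm distal (z = +30)
#' to the annulus plane, sized to cover the lumen.
#'
#' @param profile A [build_root_profile()] result.
#' @param sampling_step Plane lattice pitch, mm.
#' @return List with `proximal` and `distal` [plane_spec()]s.
#' @export
default_planes <- function(profile, sampling_step = 0.2) {
  ext <- profile$params$sinus_max_diameter / 2 + 2
  list(proximal = plane_spec(c(0, 0, -10), c(0, 0, 1), ext, sampling_step),
       distal = plane_spec(c(0, 0, 30), c(0, 0, 1), ext, sampling_step))
}

#' Circulation of a sinus vortex
#'
#' Line integral of the velocity around a circular loop centred on the
#' vortex core of one sinus, in the plane of the vortex swirl (the
#' radial-axial plane of that sinus). The loop is traversed right-handed
#' about the vortex axis (the local circumferential direction), so a
#' vortex of positive prescribed strength yields positive circulation.
#'
#' @param field A [velocity_field()] carrying `vortex_meta` (from
#'   [sample_velocity_field()] with a vortex), or explicit `center`/`axis`.
#' @param sinus_index Which sinus, `0 .. n_leaflets - 1`.
#' @param frame Frame index.
#' @param loop_radius Loop radius, mm; defaults to the vortex reference
#'   loop `sqrt(2) * core_radius`.
#' @param center,axis Optional explicit loop centre and vortex axis.
#' @param n_samples Number of points along the loop.
#' @return Circulation in cm^2/s.
#' @export
sinus_circulation <- function(field, sinus_index = 0, frame = 1,
                              loop_radius = NULL, center = NULL,
                              axis = NULL, n_samples = 360) {
  vm <- field$vortex_meta
  if (is.null(center)) {
    if (is.null(vm)) stop("field has no vortex metadata; give center/axis",
                          call. = FALSE)
    if (sinus_index < 0 || sinus_index >= nrow(vm$centers))
      stop("sinus_index out of range", call. = FALSE)
    center <- vm$centers[sinus_index + 1, ]
    axis <- vm$axes[sinus_index + 1, ]
    if (is.null(loop_radius)) loop_radius <- vm$loop_radius
  }
  if (is.null(loop_radius)) stop("loop_radius required", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  # right-handed in-plane basis (u1 x u2 = axis)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- c(ref[2] * axis[3] - ref[3] * axis[2],
          ref[3] * axis[1] - ref[1] * axis[3],
          ref[1] * axis[2] - ref[2] * axis[1])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(axis[2] * u1[3] - axis[3] * u1[2],
          axis[3] * u1[1] - axis[1] * u1[3],
          axis[1] * u1[2] - axis[2] * u1[1])
  phi <- seq(0, 2 * pi, length.out = n_samples + 1)[seq_len(n_samples)]
  pts <- sweep(outer(cos(phi) * loop_radius, u1) +
                 outer(sin(phi) * loop_radius, u2), 2, center, "+")
  nvox <- prod(field$grid$dims)
  off <- (frame - 1) * nvox
  fa <- function(a) a[off + seq_len(nvox)]
  vx <- .interp3(fa(field$vx), field$grid, pts)
  vy <- .interp3(fa(field$vy), field$grid, pts)
  vz <- .interp3(fa(field$vz), field$grid, pts)
  if (!all(attr(vx, "inside")))
    stop("circulation loop exits the grid", call. = FALSE)
  tang <- outer(-sin(phi), u1) + outer(cos(phi), u2)
  vt <- vx * tang[, 1] + vy * tang[, 2] + vz * tang[, 3]   # cm/s
  dl_cm <- (2 * pi * loop_radius / n_samples) / 10
  sum(vt * dl_cm)
}
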