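# Valve leaflet shells and the assembled phantom.
#
# The leaflet mid-surface is a loft in cylindrical coordinates between the
# U-shaped attachment curve on the root inner wall and the free edge. In the
# closed state the free edge is a quadratic Bezier from commissure to
# commissure pulled through a near-axis coaptation point, so the three free
# edges meet at the centreline with the gentle concave curvature seen from
# above; opening is a kinematic morph toward a wall-hugging open free edge.
# Thickness is applied by offsetting the mid-surface +/- t/2 along its
# normals and closing the rim with a quad band.

.rot_z <- function(ang) {
  matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
}

# mid-surface map of the canonical leaflet (centred on theta = 0).
# u in [0,1] runs commissure -> commissure, v in [0,1] attachment -> free
# edge. Returns n x 3 matrix for equal-length u, v vectors.
.leaflet_midsurface <- function(params, profile, u, v, open_fraction = 0,
                                belly = 2, coapt_radius = 0.02,
                                open_clearance = 0.5) {
  p <- params
  n <- p$n_leaflets
  h <- p$leaflet_height
  cpt <- p$coaptation_height
  sector <- 2 * pi / n
  th <- -sector / 2 + u * sector

  # attachment curve on the root inner wall (z dips to the annulus mid-sector)
  z_a <- (h - cpt) * (2 * u - 1)^2
  r_a <- profile$radius_fn(z_a, th) - p$commissure_radial_offset
  A <- cbind(r_a * cos(th), r_a * sin(th), z_a)

  # closed free edge: the two radial coaptation segments of the Y-shaped
  # closure (commissure -> centre nodule -> commissure), with a
  # tangent-matched quadratic rounding of the central corner so the offset
  # shell stays self-intersection-free
  th0 <- -sector / 2; th1 <- sector / 2
  r0 <- profile$radius_fn(h, th0) - p$commissure_radial_offset
  P0 <- c(r0 * cos(th0), r0 * sin(th0), h)
  P2 <- c(r0 * cos(th1), r0 * sin(th1), h)
  M <- c(coapt_radius, 0, h - p$leaflet_free_edge_sag)
  delta <- 0.1
  ul <- 0.5 - delta; ur <- 0.5 + delta
  Fc <- matrix(0, length(u), 3)
  seg <- function(s, A0, A1) cbind(A0[1] + s * (A1[1] - A0[1]),
                                   A0[2] + s * (A1[2] - A0[2]),
                                   A0[3] + s * (A1[3] - A0[3]))
  i1 <- u <= ul
  Fc[i1, ] <- seg(2 * u[i1], P0, M)
  i3 <- u >= ur
  Fc[i3, ] <- seg(2 * u[i3] - 1, M, P2)
  i2 <- !i1 & !i3
  if (any(i2)) {
    s <- (u[i2] - ul) / (2 * delta)
    Q0 <- P0 + 2 * ul * (M - P0)       # = G(ul)
    Q2 <- M + (2 * ur - 1) * (P2 - M)  # = G(ur)
    Fc[i2, ] <- cbind(
      (1 - s)^2 * Q0[1] + 2 * s * (1 - s) * M[1] + s^2 * Q2[1],
      (1 - s)^2 * Q0[2] + 2 * s * (1 - s) * M[2] + s^2 * Q2[2],
      (1 - s)^2 * Q0[3] + 2 * s * (1 - s) * M[3] + s^2 * Q2[3])
  }

  if (open_fraction > 0) {
    r_o <- profile$radius_fn(h, th) - p$commissure_radial_offset -
      open_clearance - p$leaflet_thickness / 2
    Fo <- cbind(r_o * cos(th), r_o * sin(th), rep(h, length(u)))
    Fe <- (1 - open_fraction) * Fc + open_fraction * Fo
  } else {
    Fe <- Fc
  }

  P <- (1 - v) * A + v * Fe
  P[, 3] <- P[, 3] - belly * sin(pi * u) * sin(pi * v) * (1 - open_fraction)
  P
}

#' Build one valve leaflet shell mesh
#'
#' Generates a closed thin shell of thickness `leaflet_thickness` for one
#' leaflet, either in the closed (coapted) state or kinematically morphed
#' open. The attachment curve lies on the root inner surface; in the closed
#' state the free-edge midpoints of adjacent leaflets meet at the
#' centreline within the coaptation tolerance (0.05 mm). Leaflet `k` is the
#' canonical leaflet rotated by `2*pi*k/n_leaflets` about the flow axis, so
#' the assembly is exactly n-fold symmetric.
#'
#' @param params A [root_params()] object.
#' @param leaflet_index Which leaflet, `0 .. n_leaflets - 1`.
#' @param state `"closed"` or `"open"`.
#' @param open_fraction Opening fraction in `[0, 1]` used when
#'   `state = "open"` (1 = fully open against the sinus wall).
#' @param profile Optional precomputed [build_root_profile()] result.
#' @param n_u,n_v Mid-surface grid resolution.
#' @param belly Downward bellying of the closed mid-surface, mm.
#' @return A watertight genus-0 [surface_mesh()] (Euler characteristic 2)
#'   with component label `"leaflet"`.
#' @export
#' @examples
#' leaf <- build_leaflet_mesh(root_params(), n_u = 24, n_v = 12)
#' euler_characteristic(leaf)
build_leaflet_mesh <- function(params, leaflet_index = 0,
                               state = c("closed", "open"),
                               open_fraction = 1, profile = NULL,
                               n_u = 64, n_v = 32, belly = 2) {
  state <- match.arg(state)
  validate_root_params(params)
  p <- params
  if (leaflet_index < 0 || leaflet_index >= p$n_leaflets)
    stop("leaflet_index must be in 0 .. n_leaflets - 1", call. = FALSE)
  if (p$leaflet_height > p$sinus_height)
    stop("geometry error: attachment curve leaves the sinus segment ",
         "(leaflet_height > sinus_height)", call. = FALSE)
  if (p$coaptation_height >= p$leaflet_height)
    stop("geometry error: coaptation_height must be < leaflet_height",
         call. = FALSE)
  if (is.null(profile)) profile <- build_root_profile(p)
  frac <- if (state == "closed") 0 else open_fraction

  us <- seq(0, 1, length.out = n_u + 1)
  vs <- seq(0, 1, length.out = n_v + 1)
  U <- rep(us, times = n_v + 1)
  V <- rep(vs, each = n_u + 1)
  mid <- .leaflet_midsurface(p, profile, U, V, open_fraction = frac,
                             belly = belly)
  # normals from parametric tangents (central differences)
  hh <- 1e-4
  Pu <- (.leaflet_midsurface(p, profile, pmin(U + hh, 1), V, frac, belly) -
           .leaflet_midsurface(p, profile, pmax(U - hh, 0), V, frac, belly))
  Pv <- (.leaflet_midsurface(p, profile, U, pmin(V + hh, 1), frac, belly) -
           .leaflet_midsurface(p, profile, U, pmax(V - hh, 0), frac, belly))
  nrm <- .rowcross(Pu, Pv)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len

  t2 <- p$leaflet_thickness / 2
  nvert <- (n_u + 1L) * (n_v + 1L)
  top <- mid + t2 * nrm
  bot <- mid - t2 * nrm
  verts <- rbind(top, bot)

  gi <- function(i, j) j * (n_u + 1L) + i + 1L   # i in 0..n_u, j in 0..n_v
  ii <- rep(0:(n_u - 1L), n_v)
  jj <- rep(0:(n_v - 1L), each = n_u)
  f_top <- rbind(cbind(gi(ii, jj), gi(ii + 1L, jj), gi(ii, jj + 1L)),
                 cbind(gi(ii + 1L, jj), gi(ii + 1L, jj + 1L), gi(ii, jj + 1L)))
  f_bot <- f_top[, c(1, 3, 2)] + nvert
  # boundary loop of the (u,v) patch, counter-clockwise
  loop <- rbind(cbind(0:n_u, 0L),
                cbind(n_u, 1:n_v),
                cbind((n_u - 1L):0L, n_v),
                cbind(0L, (n_v - 1L):1L))
  li <- gi(loop[, 1], loop[, 2])
  ln <- c(li[-1], li[1])
  f_band <- rbind(cbind(li, ln, ln + nvert),
                  cbind(li, ln + nvert, li + nvert))

  faces <- rbind(f_top, f_bot, f_band)
  surface <- c(rep("sheet_top", nrow(f_top)), rep("sheet_bottom", nrow(f_bot)),
               rep("band", nrow(f_band)))
  mesh <- surface_mesh(verts, faces,
                       component_labels = rep("leaflet", nrow(faces)),
                       surface = surface)
  if (leaflet_index != 0) {
    ang <- 2 * pi * leaflet_index / p$n_leaflets
    mesh$vertices <- mesh$vertices %*% t(.rot_z(ang))
  }
  orient_mesh(mesh)
}

#' Free-edge polyline of a leaflet
#'
#' @inheritParams build_leaflet_mesh
#' @param n Number of samples along the edge.
#' @return An n x 3 matrix of points (mm) along the leaflet free edge.
#' @export
leaflet_free_edge <- function(params, leaflet_index = 0,
                              state = c("closed", "open"), open_fraction = 1,
                              profile = NULL, n = 200) {
  state <- match.arg(state)
  if (is.null(profile)) profile <- build_root_profile(params)
  frac <- if (state == "closed") 0 else open_fraction
  u <- seq(0, 1, length.out = n)
  P <- .leaflet_midsurface(params, profile, u, rep(1, n), open_fraction = frac)
  if (leaflet_index != 0)
    P <- P %*% t(.rot_z(2 * pi * leaflet_index / params$n_leaflets))
  P
}

#' Orifice area of the opened valve
#'
#' Planar polygon area (shoelace) of the projection of all leaflet free
#' edges onto the annulus plane, the standard geometric orifice measure.
#'
#' @inheritParams build_leaflet_mesh
#' @param n_per_leaflet Free-edge samples per leaflet.
#' @return Area in mm^2.
#' @export
orifice_area <- function(params, open_fraction = 1, profile = NULL,
                         n_per_leaflet = 64) {
  if (is.null(profile)) profile <- build_root_profile(params)
  pts <- do.call(rbind, lapply(seq_len(params$n_leaflets) - 1L, function(k)
    leaflet_free_edge(params, k, state = "open",
                      open_fraction = open_fraction, profile = profile,
                      n = n_per_leaflet)))
  xy <- pts[, 1:2]
  o <- order(atan2(xy[, 2], xy[, 1]))
  xy <- xy[o, ]
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Merge meshes into a multi-component mesh
#'
#' @param meshes List of [surface_mesh()] objects.
#' @param labels Character vector of component labels, one per mesh.
#' @return A single [surface_mesh()]; components remain independently closed.
#' @export
merge_meshes <- function(meshes, labels = NULL) {
  nv <- 0L
  verts <- list(); faces <- list(); lab <- list(); surf <- list()
  for (k in seq_along(meshes)) {
    m <- meshes[[k]]
    verts[[k]] <- m$vertices
    faces[[k]] <- m$faces + nv
    lab[[k]] <- if (!is.null(labels)) rep(labels[k], nrow(m$faces))
      else m$component_labels
    surf[[k]] <- if (!is.null(m$surface)) m$surface
      else rep(NA_character_, nrow(m$faces))
    nv <- nv + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, faces),
               component_labels = unlist(lab), surface = unlist(surf))
}

#' Assemble the full valve phantom
#'
#' Builds the root wall shell plus all leaflet shells as one
#' multi-component mesh; each component is independently watertight and
#' labelled (`"wall"`, `"leaflet_1"` ... `"leaflet_n"`).
#'
#' @inheritParams build_leaflet_mesh
#' @param n_axial,n_circumferential Root shell resolution, see
#'   [build_root_mesh()].
#' @param n_u,n_v Leaflet resolution.
#' @return A [surface_mesh()] with labelled components.
#' @export
assemble_phantom <- function(params, state = c("closed", "open"),
                             open_fraction = 1, n_axial = 120,
                             n_circumferential = 192, n_u = 64, n_v = 32) {
  state <- match.arg(state)
  profile <- build_root_profile(params)
  root <- build_root_mesh(profile, params, n_axial, n_circumferential)
  leaflets <- lapply(seq_len(params$n_leaflets) - 1L, function(k)
    build_leaflet_mesh(params, k, state = state,
                       open_fraction = open_fraction, profile = profile,
                       n_u = n_u, n_v = n_v))
  m <- merge_meshes(c(list(root), leaflets),
                    labels = c("wall", paste0("leaflet_",
                                              seq_len(params$n_leaflets))))
  # keep the root's finer surface tags
  m$surface <- c(root$surface, unlist(lapply(leaflets, `[[`, "surface")))
  m
}
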