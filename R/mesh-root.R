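# Solid-wall shell of the aortic root: inner lumen surface, outer surface
# offset outward by wall_thickness along local surface normals, and annular
# end caps at the LVOT inlet and aortic outlet rims. The lumen stays open
# for flow; the closed body is the wall itself (a genus-1 shell).

#' Build the aortic-root wall shell mesh
#'
#' Sweeps the lumen radius model of [build_root_profile()] into a closed
#' solid-wall shell: the inner surface, an outer surface offset by
#' `wall_thickness` along the local surface normal, and annular caps at both
#' tube rims. Faces carry `surface` tags `"wall_inner"`, `"wall_outer"`,
#' `"cap"` and component label `"wall"`.
#'
#' @param profile A `root_profile` from [build_root_profile()].
#' @param params The [root_params()] used to build the profile.
#' @param n_axial Number of axial subdivisions (>= 8; default 120).
#' @param n_circumferential Number of circumferential subdivisions (>= 24;
#'   default 192).
#' @return A watertight, outward-oriented [surface_mesh()] of genus 1
#'   (Euler characteristic 0).
#' @export
#' @examples
#' p <- root_params()
#' m <- build_root_mesh(build_root_profile(p), p, n_axial = 24,
#'                      n_circumferential = 48)
#' is_watertight(m)
build_root_mesh <- function(profile, params, n_axial = 120,
                            n_circumferential = 192) {
  if (n_axial < 8) stop("n_axial must be >= 8", call. = FALSE)
  if (n_circumferential < 24) stop("n_circumferential must be >= 24",
                                   call. = FALSE)
  t <- params$wall_thickness
  na <- n_axial; nc <- n_circumferential
  zs <- seq(profile$z_min, profile$z_max, length.out = na + 1)
  th <- seq(0, 2 * pi, length.out = nc + 1)[seq_len(nc)]

  Z <- matrix(rep(zs, nc), na + 1, nc)
  TH <- matrix(rep(th, each = na + 1), na + 1, nc)
  R <- matrix(profile$radius_fn(as.vector(Z), as.vector(TH)), na + 1, nc)
  dRdz <- matrix(.radius_dz(profile, as.vector(Z), as.vector(TH)), na + 1, nc)
  dRdt <- matrix(.radius_dtheta(profile, as.vector(Z), as.vector(TH)),
                 na + 1, nc)

  ct <- cos(TH); st <- sin(TH)
  inner <- cbind(as.vector(R * ct), as.vector(R * st), as.vector(Z))
  # outward (away from axis) surface normal in cylindrical components
  nr <- rep(1, length(R)); nth <- as.vector(-dRdt / R); nz <- as.vector(-dRdz)
  nlen <- sqrt(nr^2 + nth^2 + nz^2)
  nx <- (nr * as.vector(ct) - nth * as.vector(st)) / nlen
  ny <- (nr * as.vector(st) + nth * as.vector(ct)) / nlen
  nzc <- nz / nlen
  outer <- inner + t * cbind(nx, ny, nzc)

  # fold guard: the offset must keep each axial ring simple (no local
  # self-intersection when wall_thickness exceeds the curvature radius)
  ro <- sqrt(outer[, 1]^2 + outer[, 2]^2)
  if (any(ro <= 0))
    stop("geometry error: wall_thickness too large for local curvature",
         call. = FALSE)
  Ro <- matrix(ro, na + 1, nc)
  tho <- matrix(atan2(outer[, 2], outer[, 1]), na + 1, nc)
  dth <- (tho[, c(2:nc, 1)] - tho) %% (2 * pi)
  if (any(dth > pi))
    stop("geometry error: wall offset self-intersects (wall_thickness too large)",
         call. = FALSE)

  idx <- function(i, j) (j - 1L) * (na + 1L) + i        # inner sheet
  odx <- function(i, j) (na + 1L) * nc + (j - 1L) * (na + 1L) + i
  jp <- function(j) ifelse(j == nc, 1L, j + 1L)

  ii <- rep(seq_len(na), nc)
  jj <- rep(seq_len(nc), each = na)
  jn <- jp(jj)
  # outer sheet: winding (theta, z) -> normal away from axis (out of solid)
  f_out <- rbind(cbind(odx(ii, jj), odx(ii, jn), odx(ii + 1L, jj)),
                 cbind(odx(ii, jn), odx(ii + 1L, jn), odx(ii + 1L, jj)))
  # inner sheet: out of the solid = toward the axis -> reversed winding
  f_in <- rbind(cbind(idx(ii, jj), idx(ii + 1L, jj), idx(ii, jn)),
                cbind(idx(ii, jn), idx(ii + 1L, jj), idx(ii + 1L, jn)))
  j1 <- seq_len(nc); j2 <- jp(j1)
  # bottom cap (z = z_min): normal -z
  f_cb <- rbind(cbind(idx(1L, j1), idx(1L, j2), odx(1L, j1)),
                cbind(idx(1L, j2), odx(1L, j2), odx(1L, j1)))
  # top cap (z = z_max): normal +z
  f_ct <- rbind(cbind(idx(na + 1L, j1), odx(na + 1L, j1), idx(na + 1L, j2)),
                cbind(idx(na + 1L, j2), odx(na + 1L, j1), odx(na + 1L, j2)))

  faces <- rbind(f_in, f_out, f_cb, f_ct)
  surface <- c(rep("wall_inner", nrow(f_in)), rep("wall_outer", nrow(f_out)),
               rep("cap", nrow(f_cb) + nrow(f_ct)))
  mesh <- surface_mesh(rbind(inner, outer), faces,
                       component_labels = rep("wall", nrow(faces)),
                       surface = surface)
  orient_mesh(mesh)
}
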