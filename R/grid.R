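# Regular voxel grid and acquisition parameters for the synthetic
# phase-contrast datasets, plus vectorised trilinear interpolation.

#' Acquisition parameters for synthetic phase-contrast data
#'
#' Describes the voxel grid, temporal resolution and velocity encoding of a
#' synthetic acquisition. Exactly two of `voxel_size` / `field_of_view` /
#' `matrix_size` determine the third; if all three are given they must be
#' consistent to within one voxel per axis.
#'
#' Defaults emulate a desk-scale 4D flow protocol (isotropic-matrix 64^3
#' grid, venc 100 cm/s); a 2D protocol is selected with `mode = "2D"` and a
#' `plane_z`, conventionally with venc 70 cm/s.
#'
#' @param voxel_size Length-3 voxel edge sizes (dx, dy, dz), mm.
#' @param field_of_view Length-3 field of view (Lx, Ly, Lz), mm.
#' @param matrix_size Length-3 integer matrix size (nx, ny, nz).
#' @param origin Coordinates of the centre of voxel (1,1,1), mm. Default
#'   centres the FoV on the flow axis laterally, with z spanning
#'   `z_range`.
#' @param z_range Length-2 axial extent covered by the grid, mm.
#' @param n_frames Frames per cardiac cycle (>= 2).
#' @param venc Velocity-encoding limit, cm/s.
#' @param noise_sd Gaussian velocity noise SD, cm/s (default 0).
#' @param mode `"4D"` or `"2D"`.
#' @param plane_z Slice position for 2D mode, mm.
#' @return An `acquisition_params` object with a `grid` element
#'   (`origin`, `voxel`, `dims`).
#' @export
acquisition_params <- function(voxel_size = NULL, field_of_view = NULL,
                               matrix_size = NULL, origin = NULL,
                               z_range = NULL, n_frames = 20, venc = 100,
                               noise_sd = 0, mode = c("4D", "2D"),
                               plane_z = NULL) {
  mode <- match.arg(mode)
  given <- !c(is.null(voxel_size), is.null(field_of_view),
              is.null(matrix_size))
  if (sum(given) < 2)
    stop("give at least two of voxel_size, field_of_view, matrix_size",
         call. = FALSE)
  if (is.null(matrix_size))
    matrix_size <- round(field_of_view / voxel_size)
  if (is.null(voxel_size)) voxel_size <- field_of_view / matrix_size
  if (is.null(field_of_view)) field_of_view <- matrix_size * voxel_size
  matrix_size <- as.integer(matrix_size)
  if (any(abs(matrix_size * voxel_size - field_of_view) > voxel_size))
    stop("inconsistent grid: matrix_size * voxel_size must equal ",
         "field_of_view within one voxel per axis", call. = FALSE)
  if (venc <= 0) stop("venc must be > 0", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(origin)) {
    z0 <- if (!is.null(z_range)) z_range[1] + voxel_size[3] / 2
      else -field_of_view[3] / 2 + voxel_size[3] / 2
    origin <- c(-field_of_view[1] / 2 + voxel_size[1] / 2,
                -field_of_view[2] / 2 + voxel_size[2] / 2, z0)
  }
  structure(list(grid = list(origin = as.numeric(origin),
                             voxel = as.numeric(voxel_size),
                             dims = matrix_size),
                 field_of_view = as.numeric(field_of_view),
                 n_frames = as.integer(n_frames), venc = venc,
                 noise_sd = noise_sd, mode = mode, plane_z = plane_z),
            class = "acquisition_params")
}

#' Default desk-scale acquisition over a phantom lumen
#'
#' Builds a 4D acquisition whose grid covers the whole lumen of `profile`
#' with a small margin: default 64^3 matrix, venc 100 cm/s.
#'
#' @param profile A [build_root_profile()] result.
#' @param matrix_size Length-3 matrix (default `c(64, 64, 64)`).
#' @param n_frames Frames per cycle.
#' @param venc Velocity encoding, cm/s.
#' @param margin Lateral margin around the widest lumen radius, mm.
#' @param ... Passed to [acquisition_params()].
#' @export
default_acquisition <- function(profile, matrix_size = c(64, 64, 64),
                                n_frames = 20, venc = 100, margin = 3,
                                ...) {
  rmax <- profile$params$sinus_max_diameter / 2 + margin
  zlen <- profile$z_max - profile$z_min + 2
  fov <- c(2 * rmax, 2 * rmax, zlen)
  acquisition_params(field_of_view = fov, matrix_size = matrix_size,
                     z_range = c(profile$z_min - 1, profile$z_max + 1),
                     n_frames = n_frames, venc = venc, ...)
}

# grid axes (voxel-centre coordinates)
.grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$voxel[1],
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$voxel[2],
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$voxel[3])
}

# Trilinear interpolation of a 3D array at points (n x 3, mm).
# Outside the grid returns `outside` and inside = FALSE.
.interp3 <- function(arr, grid, pts, outside = 0) {
  fx <- (pts[, 1] - grid$origin[1]) / grid$voxel[1] + 1
  fy <- (pts[, 2] - grid$origin[2]) / grid$voxel[2] + 1
  fz <- (pts[, 3] - grid$origin[3]) / grid$voxel[3] + 1
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  inside <- i0 >= 1 & i0 + 1 <= nx & j0 >= 1 & j0 + 1 <= ny &
    k0 >= 1 & k0 + 1 <= nz & is.finite(fx) & is.finite(fy) & is.finite(fz)
  val <- rep(outside, nrow(pts))
  if (any(inside)) {
    i0i <- i0[inside]; j0i <- j0[inside]; k0i <- k0[inside]
    wx <- fx[inside] - i0i; wy <- fy[inside] - j0i; wz <- fz[inside] - k0i
    base <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
    v000 <- arr[base(i0i,     j0i,     k0i)]
    v100 <- arr[base(i0i + 1, j0i,     k0i)]
    v010 <- arr[base(i0i,     j0i + 1, k0i)]
    v110 <- arr[base(i0i + 1, j0i + 1, k0i)]
    v001 <- arr[base(i0i,     j0i,     k0i + 1)]
    v101 <- arr[base(i0i + 1, j0i,     k0i + 1)]
    v011 <- arr[base(i0i,     j0i + 1, k0i + 1)]
    v111 <- arr[base(i0i + 1, j0i + 1, k0i + 1)]
    val[inside] <-
      (1 - wz) * ((1 - wy) * ((1 - wx) * v000 + wx * v100) +
                    wy * ((1 - wx) * v010 + wx * v110)) +
      wz * ((1 - wy) * ((1 - wx) * v001 + wx * v101) +
              wy * ((1 - wx) * v011 + wx * v111))
  }
  attr(val, "inside") <- inside
  val
}
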