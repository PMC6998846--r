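# NIfTI interchange for synthetic velocity datasets: one 4D volume per
# velocity component plus a 3D lumen mask, with a JSON manifest carrying
# the quantities NIfTI cannot (venc, frame times, units, grid origin,
# vortex metadata).

#' Export and import a velocity dataset as NIfTI
#'
#' Writes `vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz` (4D, cm/s), `mask.nii.gz`
#' and `manifest.json` into `dir`. The NIfTI pixdim encodes the voxel size
#' in mm; the grid origin, frame times, period, venc and units live in the
#' manifest. The round trip preserves values to stored (double) precision
#' and the grid geometry exactly.
#'
#' @param field A [velocity_field()].
#' @param dir Output directory (created if needed).
#' @return `export_nifti()` returns `dir` invisibly; `import_nifti()`
#'   returns the reconstructed [velocity_field()].
#' @export
export_nifti <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- if (length(field$times) > 1) diff(field$times[1:2]) else 1
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    nd <- length(dim(arr))
    RNifti::pixdim(img) <- c(field$grid$voxel, dt)[seq_len(nd)]
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wr(field$vx, "vx.nii.gz")
  wr(field$vy, "vy.nii.gz")
  wr(field$vz, "vz.nii.gz")
  wr(array(as.numeric(field$mask), dim(field$mask)), "mask.nii.gz")
  manifest <- list(units = list(velocity = "cm/s", length = "mm",
                                time = "s"),
                   origin_mm = field$grid$origin,
                   voxel_mm = field$grid$voxel,
                   dims = field$grid$dims,
                   times_s = field$times,
                   period_s = field$period,
                   venc_cm_s = field$venc,
                   noise_sd_cm_s = field$noise_sd,
                   vortex_meta = field$vortex_meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname export_nifti
#' @export
import_nifti <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, name))
    array(as.numeric(img), dim(img))
  }
  vx <- rd("vx.nii.gz"); vy <- rd("vy.nii.gz"); vz <- rd("vz.nii.gz")
  mask <- rd("mask.nii.gz")
  if (!identical(dim(vx), dim(vy)) || !identical(dim(vx), dim(vz)))
    stop("format error: velocity components have mismatched dimensions",
         call. = FALSE)
  if (length(dim(vx)) == 3) dim(vx) <- dim(vy) <- dim(vz) <- c(dim(vx), 1)
  if (dim(vx)[4] != length(man$times_s))
    stop("format error: frame count does not match manifest times",
         call. = FALSE)
  pd <- RNifti::pixdim(RNifti::readNifti(file.path(dir, "vx.nii.gz")))
  if (any(abs(pd[1:3] - man$voxel_mm) > 1e-6))
    stop("format error: NIfTI pixdim disagrees with manifest voxel size",
         call. = FALSE)
  grid <- list(origin = as.numeric(man$origin_mm),
               voxel = as.numeric(man$voxel_mm),
               dims = as.integer(man$dims))
  vm <- man$vortex_meta
  if (!is.null(vm)) {
    for (f in c("centers", "axes", "radials"))
      if (!is.null(vm[[f]])) vm[[f]] <- matrix(as.numeric(t(vm[[f]])),
                                               ncol = 3, byrow = TRUE)
  }
  fld <- velocity_field(vx, vy, vz, array(mask > 0.5, grid$dims), grid,
                        as.numeric(man$times_s), man$period_s,
                        man$venc_cm_s, vortex_meta = vm)
  fld$noise_sd <- man$noise_sd_cm_s
  fld
}
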