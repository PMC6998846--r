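#' Named dimensions of the aortic root and valve phantom
#'
#' Collects every geometric parameter of the parametric phantom: the aortic
#' root (annulus, sinuses of Valsalva, sinotubular junction, ascending aorta,
#' left ventricular outflow tract), the solid wall, and the valve leaflets.
#' All lengths are millimetres.
#'
#' The default dimensions describe a normal adult tricuspid aortic valve of
#' the annulus-23-mm class, with a 2 mm printable wall and 0.6 mm leaflets.
#' Every value can be overridden, including from a JSON configuration file
#' (see [read_root_params()]).
#'
#' @param annulus_diameter Inner diameter of the valve annulus at the leaflet
#'   attachment base plane (z = 0), mm.
#' @param sinus_max_diameter Maximum inner diameter across the sinus of
#'   Valsalva bulges, mm. Must be at least the annulus and sinotubular
#'   diameters.
#' @param sinus_height Axial extent of the sinus segment above the annulus, mm.
#' @param sinotubular_diameter Inner diameter at the sinotubular junction, mm.
#' @param ascending_aorta_diameter Inner diameter of the tubular ascending
#'   aorta, mm.
#' @param ascending_aorta_length Axial length of ascending aorta modelled
#'   above the sinotubular junction, mm.
#' @param lvot_diameter Inner diameter of the left ventricular outflow tract
#'   cylinder proximal to the annulus, mm.
#' @param lvot_length Axial length of the modelled LVOT, mm.
#' @param wall_thickness Printed wall thickness of the root shell, mm.
#' @param n_leaflets Number of valve leaflets (3 = normal tricuspid valve;
#'   2 gives a bicuspid variant).
#' @param leaflet_thickness Printed leaflet shell thickness, mm.
#' @param leaflet_height Axial height of the commissure tops above the
#'   annulus, mm. Must not exceed `sinus_height` (the attachment curve must
#'   stay on the sinus segment).
#' @param leaflet_free_edge_sag Downward sag of the free-edge midpoint below
#'   the commissure level in the closed state, mm.
#' @param coaptation_height Height of the coapting free-edge segment at the
#'   commissures, mm.
#' @param commissure_radial_offset Inward radial offset of the leaflet
#'   attachment curve from the root inner wall, mm (0 = attached on the wall).
#'
#' @return An object of class `root_params` (a validated named list).
#' @seealso [build_root_profile()], [build_root_mesh()], [build_leaflet_mesh()]
#' @export
#' @examples
#' p <- root_params()
#' p$annulus_diameter
root_params <- function(annulus_diameter = 23,
                        sinus_max_diameter = 34,
                        sinus_height = 22,
                        sinotubular_diameter = 27,
                        ascending_aorta_diameter = 29,
                        ascending_aorta_length = 40,
                        lvot_diameter = 23,
                        lvot_length = 20,
                        wall_thickness = 2.0,
                        n_leaflets = 3,
                        leaflet_thickness = 0.6,
                        leaflet_height = 14,
                        leaflet_free_edge_sag = 2.5,
                        coaptation_height = 4,
                        commissure_radial_offset = 0) {
  p <- list(
    annulus_diameter = annulus_diameter,
    sinus_max_diameter = sinus_max_diameter,
    sinus_height = sinus_height,
    sinotubular_diameter = sinotubular_diameter,
    ascending_aorta_diameter = ascending_aorta_diameter,
    ascending_aorta_length = ascending_aorta_length,
    lvot_diameter = lvot_diameter,
    lvot_length = lvot_length,
    wall_thickness = wall_thickness,
    n_leaflets = n_leaflets,
    leaflet_thickness = leaflet_thickness,
    leaflet_height = leaflet_height,
    leaflet_free_edge_sag = leaflet_free_edge_sag,
    coaptation_height = coaptation_height,
    commissure_radial_offset = commissure_radial_offset
  )
  class(p) <- "root_params"
  validate_root_params(p)
  p
}

#' Validate phantom geometry parameters
#'
#' Checks every invariant of [root_params()] and stops with an error naming
#' the offending field on the first violation.
#'
#' @param p A `root_params` object (or bare named list with the same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_root_params <- function(p) {
  lengths <- c("annulus_diameter", "sinus_max_diameter", "sinus_height",
               "sinotubular_diameter", "ascending_aorta_diameter",
               "ascending_aorta_length", "lvot_diameter", "lvot_length",
               "wall_thickness", "leaflet_thickness", "leaflet_height")
  for (f in c(lengths, "n_leaflets", "leaflet_free_edge_sag",
              "coaptation_height", "commissure_radial_offset")) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("invalid parameter '", f, "': must be a single finite number",
           call. = FALSE)
  }
  for (f in lengths)
    if (p[[f]] <= 0)
      stop("invalid parameter '", f, "': length must be > 0", call. = FALSE)
  if (p$leaflet_free_edge_sag < 0)
    stop("invalid parameter 'leaflet_free_edge_sag': must be >= 0",
         call. = FALSE)
  if (p$coaptation_height < 0)
    stop("invalid parameter 'coaptation_height': must be >= 0", call. = FALSE)
  if (p$commissure_radial_offset < 0)
    stop("invalid parameter 'commissure_radial_offset': must be >= 0",
         call. = FALSE)
  if (p$wall_thickness >= p$annulus_diameter / 4)
    stop("invalid parameter 'wall_thickness': must be < annulus_diameter/4",
         call. = FALSE)
  if (p$leaflet_thickness >= p$wall_thickness)
    stop("invalid parameter 'leaflet_thickness': must be < wall_thickness",
         call. = FALSE)
  if (p$sinus_max_diameter < p$annulus_diameter)
    stop("invalid parameter 'sinus_max_diameter': must be >= annulus_diameter",
         call. = FALSE)
  if (p$sinus_max_diameter < p$sinotubular_diameter)
    stop("invalid parameter 'sinus_max_diameter': must be >= sinotubular_diameter",
         call. = FALSE)
  if (p$n_leaflets < 2 || p$n_leaflets != round(p$n_leaflets))
    stop("invalid parameter 'n_leaflets': must be an integer >= 2",
         call. = FALSE)
  invisible(p)
}

#' @export
print.root_params <- function(x, ...) {
  cat("Aortic root phantom parameters (mm):\n")
  for (f in names(x)) cat(sprintf("  %-26s %g\n", f, x[[f]]))
  invisible(x)
}

#' Read and write phantom parameters as JSON
#'
#' The JSON schema is flat: one key per [root_params()] field. Missing keys
#' take the package defaults; unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return `read_root_params()` returns a validated `root_params` object.
#' @export
read_root_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(root_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown parameter field(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(root_params, cfg)
}

#' @rdname read_root_params
#' @param p A `root_params` object.
#' @export
write_root_params <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
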