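# STL import/export. Binary STL: 80-byte header, uint32 triangle count,
# then per facet 12 little-endian float32 (normal + 3 vertices) and a
# uint16 attribute. STL itself is unit-less; a JSON sidecar records the
# millimetre convention and the coordinate frame (z = flow axis, origin at
# the annulus plane).

#' Export a mesh as STL
#'
#' Writes binary (default) or ASCII STL. Facet normals are recomputed from
#' the vertex winding. A JSON metadata sidecar (`<path>.json`) documents
#' units, the coordinate convention and optional parameter provenance.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @param ascii Write the ASCII dialect instead of binary.
#' @param sidecar Write the JSON metadata sidecar (default TRUE).
#' @param provenance Optional list recorded in the sidecar (e.g. the
#'   [root_params()] used).
#' @return `path`, invisibly.
#' @export
export_stl <- function(mesh, path, ascii = FALSE, sidecar = TRUE,
                       provenance = NULL) {
  if (nrow(mesh$faces) == 0) stop("empty mesh", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot write ", path, ": directory does not exist", call. = FALSE)
  nrm <- face_normals(mesh)
  fc <- .face_corners(mesh)
  nf <- nrow(mesh$faces)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid valvephantom", con)
    block <- sprintf(paste0(
      "facet normal %.9e %.9e %.9e\n outer loop\n",
      "  vertex %.9e %.9e %.9e\n  vertex %.9e %.9e %.9e\n",
      "  vertex %.9e %.9e %.9e\n endloop\nendfacet"),
      nrm[, 1], nrm[, 2], nrm[, 3],
      fc$a[, 1], fc$a[, 2], fc$a[, 3],
      fc$b[, 1], fc$b[, 2], fc$b[, 3],
      fc$c[, 1], fc$c[, 2], fc$c[, 3])
    writeLines(block, con)
    writeLines("endsolid valvephantom", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("valvephantom binary STL (units mm)",
                                width = 80, flag = "-"))
    writeBin(header[1:80], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # interleave: per facet 12 floats then attribute uint16 (= two zero bytes)
    dat <- rbind(t(nrm), t(fc$a), t(fc$b), t(fc$c))   # 12 x nf
    raw12 <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    m <- matrix(raw12, nrow = 48)                      # 48 bytes per facet
    out <- rbind(m, matrix(as.raw(0), 2, nf))
    writeBin(as.vector(out), con)
  }
  if (sidecar) {
    meta <- list(format = if (ascii) "stl-ascii" else "stl-binary",
                 units = "mm",
                 coordinate_convention = paste(
                   "right-handed; z = flow axis; z = 0 at annulus plane;",
                   "positive z toward aorta"),
                 n_triangles = nf,
                 provenance = provenance)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Import an STL file
#'
#' Sniffs the dialect (ASCII files begin with `solid` and contain `facet`
#' tokens; anything else is treated as binary), parses the triangles and
#' welds coincident vertices to recover connectivity.
#'
#' @param path STL file path.
#' @param weld_tol Vertex welding tolerance, mm.
#' @return A [surface_mesh()].
#' @export
import_stl <- function(path, weld_tol = 1e-9) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  head <- readBin(path, "raw", n = 512)
  txt_head <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head, useBytes = TRUE) &&
    grepl("facet", txt_head, useBytes = TRUE)
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path)
  nf <- nrow(tri) / 3
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  weld_vertices(surface_mesh(tri, faces), tol = weld_tol)
}

.read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84)
    stop("malformed binary STL ", path, ": file truncated at byte ", sz,
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * nf
  if (sz != expected)
    stop("malformed binary STL ", path, ": expected ", expected,
         " bytes for ", nf, " facets, found ", sz, " (error at byte 80)",
         call. = FALSE)
  body <- readBin(con, "raw", n = 50 * nf)
  m <- matrix(body, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12 * nf, size = 4,
                    endian = "little")
  fm <- matrix(floats, nrow = 12)     # normal + v1 + v2 + v3 per column
  tri <- t(fm[4:12, , drop = FALSE])  # nf x 9
  matrix(t(tri), ncol = 3, byrow = TRUE)
}

.read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex", txt, value = TRUE)
  if (!length(vlines) || length(vlines) %% 3 != 0)
    stop("malformed ASCII STL ", path, ": vertex count not a multiple of 3",
         call. = FALSE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(w)
    as.numeric(w[2:4])))
  if (anyNA(nums))
    stop("malformed ASCII STL ", path, ": unparseable vertex line",
         call. = FALSE)
  nums
}
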