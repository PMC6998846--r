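# Triangle-mesh representation and diagnostics.
#
# A surface_mesh holds vertices (n x 3 matrix, mm), faces (m x 3 integer
# matrix of vertex indices, counter-clockwise seen from outside the solid)
# and optional per-face component labels. Finalised meshes are closed
# oriented 2-manifolds; the mesh of a tube wall is genus 1 (Euler
# characteristic 0), thin closed shells are genus 0 (characteristic 2).

#' Construct a triangle surface mesh
#'
#' @param vertices Numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces Integer matrix, one row per triangle, vertex indices
#'   (1-based), counter-clockwise when viewed from outside the solid.
#' @param component_labels Optional character vector, one label per face
#'   (e.g. `"wall"`, `"leaflet_1"`).
#' @param surface Optional character vector, one finer surface tag per face
#'   (e.g. `"wall_inner"`, `"wall_outer"`, `"cap"`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, component_labels = NULL,
                         surface = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(component_labels) && length(component_labels) != nrow(faces))
    stop("component_labels must have one entry per face")
  if (!is.null(surface) && length(surface) != nrow(faces))
    stop("surface tags must have one entry per face")
  structure(list(vertices = vertices, faces = faces,
                 component_labels = component_labels, surface = surface),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  if (!is.null(x$component_labels))
    cat(sprintf(", components: %s",
                paste(unique(x$component_labels), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# ---- basic per-face quantities ------------------------------------------

.face_corners <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

.rowcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-face normals, centroids and areas
#'
#' @param mesh A [surface_mesh()].
#' @return `face_normals()`: m x 3 matrix of unit normals (right-hand rule
#'   from the vertex winding); `face_centroids()`: m x 3 matrix;
#'   `face_areas()`: numeric vector, mm^2.
#' @export
face_normals <- function(mesh) {
  fc <- .face_corners(mesh)
  n <- .rowcross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname face_normals
#' @export
face_centroids <- function(mesh) {
  fc <- .face_corners(mesh)
  (fc$a + fc$b + fc$c) / 3
}

#' @rdname face_normals
#' @export
face_areas <- function(mesh) {
  fc <- .face_corners(mesh)
  0.5 * sqrt(rowSums(.rowcross(fc$b - fc$a, fc$c - fc$a)^2))
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive when all
#' faces are wound outward.
#'
#' @param mesh A closed [surface_mesh()].
#' @return Volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  fc <- .face_corners(mesh)
  sum(rowSums(fc$a * .rowcross(fc$b, fc$c))) / 6
}

# per-component signed volumes given a face -> component id vector
.component_volumes <- function(mesh, fcomp) {
  fc <- .face_corners(mesh)
  contrib <- rowSums(fc$a * .rowcross(fc$b, fc$c)) / 6
  as.numeric(tapply(contrib, fcomp, sum))
}

# ---- topology ------------------------------------------------------------

# directed edge table: one row per half-edge
.edge_table <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  face <- rep.int(seq_len(nrow(f)), 3)
  key <- paste(pmin(from, to), pmax(from, to))
  list(from = from, to = to, face = face, key = key,
       dir = ifelse(from < to, 1L, -1L))
}

#' Topological checks on a triangle mesh
#'
#' `is_edge_manifold()` checks that every undirected edge is shared by
#' exactly two faces. `is_watertight()` additionally requires the two
#' half-edges to run in opposite directions (consistent orientation, no
#' boundary). `euler_characteristic()` returns V - E + F over the vertices
#' actually referenced.
#'
#' @param mesh A [surface_mesh()].
#' @return Logical (or integer for the characteristic).
#' @export
is_edge_manifold <- function(mesh) {
  et <- .edge_table(mesh)
  all(table(et$key) == 2L)
}

#' @rdname is_edge_manifold
#' @export
is_watertight <- function(mesh) {
  et <- .edge_table(mesh)
  tab <- table(et$key)
  if (!all(tab == 2L)) return(FALSE)
  s <- tapply(et$dir, et$key, sum)
  all(s == 0L)
}

#' @rdname is_edge_manifold
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$faces)))
  et <- .edge_table(mesh)
  e <- length(unique(et$key))
  v - e + nrow(mesh$faces)
}

# connected components of faces (shared-edge connectivity) and consistent
# orientation by breadth-first propagation. Returns list(fcomp, flip).
.face_components_orient <- function(mesh) {
  nf <- nrow(mesh$faces)
  et <- .edge_table(mesh)
  o <- order(et$key)
  key_s <- et$key[o]; face_s <- et$face[o]; dir_s <- et$dir[o]
  grp <- cumsum(!duplicated(key_s))
  # pair up half-edges: for manifold meshes each group has exactly 2
  first <- !duplicated(grp)
  second <- rev(!duplicated(rev(grp)))
  if (!all(tabulate(grp) == 2L))
    stop("mesh is not edge-manifold; cannot orient", call. = FALSE)
  fa <- face_s[first];  da <- dir_s[first]
  fb <- face_s[second]; db <- dir_s[second]
  # adjacency with parity: need_flip when the two half-edges run the same way
  same <- da == db
  nbr <- vector("list", nf)
  par <- vector("list", nf)
  idx <- seq_along(fa)
  nbr_from <- c(fa, fb); nbr_to <- c(fb, fa); nbr_same <- c(same, same)
  ordf <- order(nbr_from)
  nbr_from <- nbr_from[ordf]; nbr_to <- nbr_to[ordf]; nbr_same <- nbr_same[ordf]
  starts <- c(which(!duplicated(nbr_from)), length(nbr_from) + 1L)
  present <- unique(nbr_from)
  look <- integer(nf); look[present] <- seq_along(present)

  fcomp <- integer(nf)
  sign <- integer(nf) # +1 keep, -1 flip
  comp <- 0L
  for (seed in seq_len(nf)) {
    if (fcomp[seed] != 0L) next
    comp <- comp + 1L
    fcomp[seed] <- comp; sign[seed] <- 1L
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (fcur in frontier) {
        li <- look[fcur]
        if (li == 0L) next
        rng <- starts[li]:(starts[li + 1L] - 1L)
        for (r in rng) {
          g <- nbr_to[r]
          want <- if (nbr_same[r]) -sign[fcur] else sign[fcur]
          if (fcomp[g] == 0L) {
            fcomp[g] <- comp; sign[g] <- want
            nxt <- c(nxt, g)
          } else if (sign[g] != want) {
            stop("mesh is not orientable", call. = FALSE)
          }
        }
      }
      frontier <- nxt
    }
  }
  list(fcomp = fcomp, flip = sign < 0L)
}

#' Orient a closed mesh consistently outward
#'
#' Propagates a consistent winding across each connected component (flipping
#' faces where needed) and then flips whole components whose signed volume
#' is negative, so that all faces point out of the solid.
#'
#' @param mesh An edge-manifold [surface_mesh()].
#' @return The oriented mesh, with a `fcomp` element giving the face
#'   component index.
#' @export
orient_mesh <- function(mesh) {
  co <- .face_components_orient(mesh)
  f <- mesh$faces
  if (any(co$flip)) f[co$flip, c(2, 3)] <- f[co$flip, c(3, 2)]
  mesh$faces <- f
  vols <- .component_volumes(mesh, co$fcomp)
  neg <- which(vols < 0)
  if (length(neg)) {
    fl <- co$fcomp %in% neg
    mesh$faces[fl, c(2, 3)] <- mesh$faces[fl, c(3, 2)]
  }
  mesh$fcomp <- co$fcomp
  mesh
}

#' Merge coincident vertices and drop degenerate faces
#'
#' @param mesh A [surface_mesh()].
#' @param tol Coordinates are rounded to this grid before matching, mm.
#' @return The welded mesh.
#' @export
weld_vertices <- function(mesh, tol = 1e-9) {
  v <- round(mesh$vertices / tol) * tol
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- mesh$vertices[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  surface_mesh(newv, f[ok, , drop = FALSE],
               component_labels = mesh$component_labels[ok],
               surface = mesh$surface[ok])
}

# ---- ray casting ---------------------------------------------------------

# First-hit distances of rays against the mesh (Moller-Trumbore), using a
# uniform-grid bucket over face centroids to prune candidates. Rays that
# find no hit within the search radius fall back to an exhaustive scan.
# origins/dirs: n x 3; src_faces: face index to exclude (with its vertex
# ring) per ray, or NA. Returns numeric vector of distances (Inf = no hit).
.ray_first_hits <- function(mesh, origins, dirs, src_faces = NULL,
                            search_radius = 6, opposing = FALSE,
                            groups = NULL) {
  fc <- .face_corners(mesh)
  v0 <- fc$a; e1 <- fc$b - fc$a; e2 <- fc$c - fc$a
  fnrm <- if (opposing) face_normals(mesh) else NULL
  cent <- (fc$a + fc$b + fc$c) / 3
  nf <- nrow(v0)
  nray <- nrow(origins)
  cell <- search_radius
  cmin <- apply(mesh$vertices, 2, min) - cell
  ci <- floor(sweep(cent, 2, cmin) / cell)
  ckey <- paste(ci[, 1], ci[, 2], ci[, 3])
  buckets <- split(seq_len(nf), ckey)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  fverts <- mesh$faces

  hit_one <- function(o, d, cand, excl_verts, grp) {
    if (!is.null(groups) && !is.na(grp)) cand <- cand[groups[cand] == grp]
    if (!length(cand)) return(Inf)
    a <- v0[cand, , drop = FALSE]
    E1 <- e1[cand, , drop = FALSE]; E2 <- e2[cand, , drop = FALSE]
    pv <- .rowcross(matrix(d, length(cand), 3, byrow = TRUE), E2)
    det <- rowSums(E1 * pv)
    tv <- sweep(-a, 2, -o)          # o - a
    u <- rowSums(tv * pv) / det
    qv <- .rowcross(tv, E1)
    vv <- rowSums(matrix(d, length(cand), 3, byrow = TRUE) * qv) / det
    tt <- rowSums(E2 * qv) / det
    ok <- is.finite(u) & abs(det) > 1e-14 &
      u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-6
    if (!is.null(fnrm)) {
      # hit must lie on the opposite shell surface: its outward normal
      # roughly aligned with the ray (which travels into the solid)
      ok <- ok & (fnrm[cand, 1] * d[1] + fnrm[cand, 2] * d[2] +
                    fnrm[cand, 3] * d[3]) >= 0.5
    }
    if (!is.null(excl_verts)) {
      shares <- (fverts[cand, 1] %in% excl_verts) |
        (fverts[cand, 2] %in% excl_verts) |
        (fverts[cand, 3] %in% excl_verts)
      ok <- ok & !shares
    }
    if (!any(ok)) return(Inf)
    min(tt[ok])
  }

  out <- numeric(nray)
  for (i in seq_len(nray)) {
    o <- origins[i, ]; d <- dirs[i, ]
    oc <- floor((o - cmin) / cell)
    keys <- paste(oc[1] + off[, 1], oc[2] + off[, 2], oc[3] + off[, 3])
    cand <- unlist(buckets[keys], use.names = FALSE)
    excl <- if (!is.null(src_faces) && !is.na(src_faces[i]))
      fverts[src_faces[i], ] else NULL
    grp <- if (!is.null(groups) && !is.null(src_faces))
      groups[src_faces[i]] else NA
    t1 <- hit_one(o, d, cand, excl, grp)
    if (!is.finite(t1) || t1 > search_radius)
      t1 <- hit_one(o, d, seq_len(nf), excl, grp)
    out[i] <- t1
  }
  out
}

#' Minimum shell thickness by inward ray casting
#'
#' Casts a ray from each face centroid along the inward face normal
#' (-normal) to its first hit on the opposite shell surface (a hit counts
#' when the hit face's outward normal opposes the source normal, which
#' excludes corner-grazing band hits) and returns the minimum distance.
#' On labelled multi-component meshes (possibly overlapping unions such as
#' the assembled phantom) rays only intersect their own component, so the
#' result is the thinnest labelled shell. For large meshes the centroids
#' are subsampled with a deterministic stride (`max_rays` cap); a
#' uniform-thickness shell gives the same minimum under subsampling.
#'
#' @param mesh A closed, outward-oriented [surface_mesh()].
#' @param max_rays Maximum number of rays to cast (deterministic stride).
#' @param faces Optional integer vector restricting source faces.
#' @return `mesh_min_thickness()`: minimum first-hit distance, mm.
#' @export
mesh_min_thickness <- function(mesh, max_rays = 4000, faces = NULL) {
  d <- .thickness_distances(mesh, max_rays, faces)
  min(d[is.finite(d)])
}

.thickness_distances <- function(mesh, max_rays = 4000, faces = NULL) {
  nf <- nrow(mesh$faces)
  src <- if (is.null(faces)) seq_len(nf) else faces
  if (length(src) > max_rays)
    src <- src[seq(1, length(src), length.out = max_rays)]
  src <- unique(as.integer(src))
  cent <- face_centroids(mesh)[src, , drop = FALSE]
  nrm <- face_normals(mesh)[src, , drop = FALSE]
  # on multi-component meshes (possibly overlapping unions) thickness is a
  # per-component property: a ray only hits faces of its own component
  groups <- if (!is.null(mesh$component_labels))
    match(mesh$component_labels, unique(mesh$component_labels)) else NULL
  .ray_first_hits(mesh, cent, -nrm, src_faces = src, opposing = TRUE,
                  groups = groups)
}

#' Wall-thickness statistics of the root shell
#'
#' Measures the inner-to-outer surface offset of a shell generated by
#' [build_root_mesh()]: from the centroid of each inner-surface face a ray
#' is cast through the wall (along the outward wall direction, i.e. the
#' inward face normal of the inner surface) to the outer surface, and the
#' distances are summarised.
#'
#' @param mesh A root shell mesh carrying `surface` tags (`"wall_inner"`).
#' @param max_rays Deterministic cap on the number of rays.
#' @return List with `median`, `mean`, `min`, `max` distance in mm and the
#'   raw `distances`.
#' @export
wall_thickness_stats <- function(mesh, max_rays = 4000) {
  if (is.null(mesh$surface) || !any(mesh$surface == "wall_inner"))
    stop("mesh has no 'wall_inner' surface tags", call. = FALSE)
  src <- which(mesh$surface == "wall_inner")
  d <- .thickness_distances(mesh, max_rays, faces = src)
  d <- d[is.finite(d)]
  list(median = stats::median(d), mean = mean(d), min = min(d), max = max(d),
       distances = d)
}

#' Printability diagnostics of a phantom mesh
#'
#' @param mesh A [surface_mesh()] (possibly several closed components).
#' @param max_rays Cap on thickness rays, see [mesh_min_thickness()].
#' @return List with `watertight` (logical), `euler_characteristic`
#'   (integer, summed over components), `volume_mm3` (signed), and
#'   `min_thickness_mm`, `n_components`.
#' @export
mesh_diagnostics <- function(mesh, max_rays = 4000) {
  if (nrow(mesh$faces) == 0) stop("empty mesh", call. = FALSE)
  wt <- is_watertight(mesh)
  ncomp <- tryCatch(length(unique(.face_components_orient(mesh)$fcomp)),
                    error = function(e) NA_integer_)
  list(watertight = wt,
       euler_characteristic = euler_characteristic(mesh),
       volume_mm3 = mesh_volume(mesh),
       min_thickness_mm = if (wt) mesh_min_thickness(mesh, max_rays) else NA_real_,
       n_components = ncomp)
}

# ---- reference solids ----------------------------------------------------

#' Icosphere test solid
#'
#' Unit-radius sphere mesh by icosahedron subdivision; a standard reference
#' for volume and topology checks.
#'
#' @param subdivisions Number of 4-to-1 triangle subdivisions (default 3).
#' @param radius Sphere radius (default 1).
#' @return A [surface_mesh()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4, 3)
    mid_env <- new.env(hash = TRUE)
    getmid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid_env[[key]]
      if (is.null(m)) {
        v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
        m <- nrow(v)
        mid_env[[key]] <- m
      }
      m
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(cc, ca, bc)
      newf[4 * k, ]     <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  orient_mesh(surface_mesh(v, f))
}
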