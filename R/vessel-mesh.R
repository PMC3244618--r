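#' Vessel wall as a triangulated surface
#'
#' A `vessel_mesh` stores a triangulated blood-vessel wall together with the
#' per-triangle plane that the contact-penalty energy evaluates. Each
#' triangle's plane is written `{x : n . x + d = 0}` with the unit normal `n`
#' oriented toward the lumen interior, so that [signed_distance()] is positive
#' on the lumen side and negative beyond the wall.
#'
#' @param vertices numeric matrix, one vertex per row, columns x/y/z in mm.
#' @param triangles integer matrix, one triangle per row, three 1-based vertex
#'   indices per row.
#' @param normals optional numeric matrix of per-triangle unit normals
#'   (inward). When omitted they are computed from the winding order; callers
#'   that need a guaranteed inward orientation should use [orient_inward()] or
#'   the generators, which orient analytically.
#'
#' @return an object of class `vessel_mesh` with fields `vertices`,
#'   `triangles`, `normals` and `offsets` (the per-triangle plane constants
#'   `d`).
#' @seealso [make_tube()], [load_mesh()], [triangle_plane()],
#'   [signed_distance()]
#' @export
vessel_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as_xyz_matrix(vertices, "vertices")
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (nrow(triangles) == 0L) {
    stop("empty mesh: no triangles", call. = FALSE)
  }
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle index out of range", call. = FALSE)
  }
  # drop degenerate (near-zero-area) triangles: they define no plane
  areas <- triangle_areas(vertices, triangles)
  degen <- areas < 1e-12
  if (any(degen)) {
    warning(sprintf("dropping %d degenerate triangle(s)", sum(degen)),
            call. = FALSE)
    triangles <- triangles[!degen, , drop = FALSE]
    if (!is.null(normals)) normals <- normals[!degen, , drop = FALSE]
    if (nrow(triangles) == 0L) stop("empty mesh: no triangles", call. = FALSE)
  }
  if (is.null(normals)) {
    normals <- winding_normals(vertices, triangles)
  } else {
    normals <- as_xyz_matrix(normals, "normals")
    normals <- normals / sqrt(rowSums(normals^2))
  }
  offsets <- -rowSums(normals * vertices[triangles[, 1L], , drop = FALSE])
  structure(
    list(vertices = vertices, triangles = triangles,
         normals = normals, offsets = offsets),
    class = "vessel_mesh")
}

#' @export
print.vessel_mesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("vessel_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  cat(sprintf("  bbox [mm]: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  if (anyNA(x)) stop(sprintf("%s contain NA", what), call. = FALSE)
  dimnames(x) <- NULL
  x
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  e1 <- vertices[triangles[, 2L], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3L], , drop = FALSE] - a
  cr <- row_cross(e1, e2)
  0.5 * sqrt(rowSums(cr^2))
}

winding_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  e1 <- vertices[triangles[, 2L], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3L], , drop = FALSE] - a
  cr <- row_cross(e1, e2)
  cr / sqrt(rowSums(cr^2))
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Plane of a vessel triangle
#'
#' Returns the stored inward-oriented plane coefficients of one triangle:
#' the unit normal `n` and offset `d` with the plane `{x : n . x + d = 0}`.
#'
#' @param mesh a [vessel_mesh()].
#' @param tri 1-based triangle index.
#' @return list with elements `normal` (unit 3-vector) and `offset` (scalar).
#' @export
triangle_plane <- function(mesh, tri) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  tri <- as.integer(tri)
  if (length(tri) != 1L || is.na(tri) || tri < 1L || tri > nrow(mesh$triangles)) {
    stop("triangle index out of range", call. = FALSE)
  }
  list(normal = mesh$normals[tri, ], offset = mesh$offsets[tri])
}

#' Signed distance of a point to a vessel triangle's plane
#'
#' Evaluates `g(p) = n . p + d` for the triangle's inward-oriented plane:
#' positive on the lumen side, zero on the wall, negative beyond it. The
#' magnitude of a negative value is the penetration depth that enters the
#' wall-penalty energy.
#'
#' @param mesh a [vessel_mesh()].
#' @param tri 1-based triangle index.
#' @param p numeric 3-vector (mm).
#' @return scalar signed distance in mm.
#' @export
signed_distance <- function(mesh, tri, p) {
  pl <- triangle_plane(mesh, tri)
  sum(pl$normal * p) + pl$offset
}

#' Apply a rigid transform to a mesh
#'
#' Rotates and translates every vertex (`x -> R x + s`) and transforms the
#' stored planes consistently, so signed distances are preserved when the same
#' transform is applied to query points.
#'
#' @param mesh a [vessel_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector.
#' @return the transformed `vessel_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  n <- mesh$normals %*% t(rotation)
  out <- mesh
  out$vertices <- v
  out$normals <- n
  out$offsets <- -rowSums(n * v[mesh$triangles[, 1L], , drop = FALSE])
  out
}

#' Re-orient triangle normals toward the lumen interior
#'
#' For meshes loaded from files the winding order carries no reliable
#' orientation. For each triangle a ray is cast from just inside its current
#' normal direction along that normal; if the ray crosses the surface an odd
#' number of times the normal points into the enclosed lumen and is kept,
#' otherwise it is flipped. This parity test also handles open tubes (the ray
#' from an inward normal crosses the far wall once; from an outward normal it
#' escapes without crossing).
#'
#' @param mesh a [vessel_mesh()].
#' @param eps offset (mm) from the centroid along the normal before casting.
#' @return the mesh with consistently inward normals and recomputed offsets.
#' @export
orient_inward <- function(mesh, eps = 1e-6) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  m <- nrow(mesh$triangles)
  tris <- mesh$triangles
  cent <- (mesh$vertices[tris[, 1L], , drop = FALSE] +
           mesh$vertices[tris[, 2L], , drop = FALSE] +
           mesh$vertices[tris[, 3L], , drop = FALSE]) / 3
  flip <- logical(m)
  for (i in seq_len(m)) {
    n <- mesh$normals[i, ]
    hits <- count_ray_hits(mesh, cent[i, ] + eps * n, n, skip = i)
    flip[i] <- (hits %% 2L) == 0L
  }
  out <- mesh
  out$normals[flip, ] <- -out$normals[flip, , drop = FALSE]
  out$offsets <- -rowSums(out$normals *
                          out$vertices[tris[, 1L], , drop = FALSE])
  out
}

# Moller-Trumbore ray/triangle intersection count, vectorized over triangles.
count_ray_hits <- function(mesh, origin, dir, skip = 0L, tmin = 1e-9) {
  tris <- mesh$triangles
  v0 <- mesh$vertices[tris[, 1L], , drop = FALSE]
  e1 <- mesh$vertices[tris[, 2L], , drop = FALSE] - v0
  e2 <- mesh$vertices[tris[, 3L], , drop = FALSE] - v0
  dmat <- matrix(dir, nrow(tris), 3, byrow = TRUE)
  pvec <- row_cross(dmat, e2)
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- sweep(v0, 2, origin, "-") * -1
  u <- rowSums(tvec * pvec) / det
  qvec <- row_cross(tvec, e1)
  v <- rowSums(dmat * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & tt > tmin
  if (skip > 0L) hit[skip] <- FALSE
  sum(hit)
}
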