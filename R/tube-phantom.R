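#' Specification of a tube phantom
#'
#' Describes a straight or curved circular tube used as a synthetic vessel
#' phantom — the in-silico analogue of the transparent plastic tubes used to
#' benchmark catheter simulators. A curved tube is an entry straight, a
#' planar circular bend, and an exit straight, swept with a circular cross
#' section.
#'
#' @param radius tube (lumen) radius in mm, > 0.
#' @param length total centerline length in mm (straight tube).
#' @param bend_radius radius of the circular bend in mm (curved tube).
#' @param bend_angle bend angle in radians, >= 0 (curved tube; 0 degenerates
#'   to a straight tube of the same total length).
#' @param entry_length,exit_length straight lengths before/after the bend, mm.
#' @param circumferential_resolution number of vertices around the cross
#'   section, >= 6.
#' @param axial_resolution number of segments along the centerline, >= 2.
#' @param capped_end close the far end with a triangle fan.
#' @return an object of class `tube_spec`.
#' @export
tube_spec <- function(radius,
                      length = NULL,
                      bend_radius = NULL,
                      bend_angle = NULL,
                      entry_length = 0,
                      exit_length = 0,
                      circumferential_resolution = 16L,
                      axial_resolution = 20L,
                      capped_end = FALSE) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive scalar", call. = FALSE)
  }
  circumferential_resolution <- as.integer(circumferential_resolution)
  axial_resolution <- as.integer(axial_resolution)
  if (circumferential_resolution < 6L) {
    stop("circumferential_resolution must be >= 6", call. = FALSE)
  }
  if (axial_resolution < 2L) stop("axial_resolution must be >= 2", call. = FALSE)
  curved <- !is.null(bend_radius) || !is.null(bend_angle)
  if (curved) {
    if (is.null(bend_radius) || is.null(bend_angle)) {
      stop("curved tube needs both bend_radius and bend_angle", call. = FALSE)
    }
    if (bend_radius <= 0 || bend_angle < 0) {
      stop("bend_radius must be > 0 and bend_angle >= 0", call. = FALSE)
    }
    if (entry_length < 0 || exit_length < 0) {
      stop("entry/exit lengths must be >= 0", call. = FALSE)
    }
  } else {
    if (is.null(length) || length <= 0) {
      stop("straight tube needs length > 0", call. = FALSE)
    }
  }
  structure(
    list(radius = radius, length = length, bend_radius = bend_radius,
         bend_angle = bend_angle, entry_length = entry_length,
         exit_length = exit_length,
         circumferential_resolution = circumferential_resolution,
         axial_resolution = axial_resolution,
         capped_end = isTRUE(capped_end), curved = curved),
    class = "tube_spec")
}

# Centerline of the tube at arc-length fractions u in [0,1]:
# positions, unit tangents, and in-plane normals (the bend lives in the
# xy-plane; the binormal is the +z axis throughout).
tube_centerline <- function(spec, u) {
  total <- tube_total_length(spec)
  s <- u * total
  n <- length(s)
  pos <- matrix(0, n, 3)
  tan <- matrix(0, n, 3)
  if (!spec$curved || spec$bend_angle == 0) {
    pos[, 1] <- s
    tan[, 1] <- 1
  } else {
    l1 <- spec$entry_length
    arc <- spec$bend_radius * spec$bend_angle
    for (i in seq_len(n)) {
      si <- s[i]
      if (si <= l1) {
        pos[i, ] <- c(si, 0, 0)
        tan[i, ] <- c(1, 0, 0)
      } else if (si <= l1 + arc) {
        phi <- (si - l1) / spec$bend_radius
        # bend center at (l1, bend_radius, 0); curve turns from +x toward +y
        pos[i, ] <- c(l1 + spec$bend_radius * sin(phi),
                      spec$bend_radius * (1 - cos(phi)), 0)
        tan[i, ] <- c(cos(phi), sin(phi), 0)
      } else {
        phi <- spec$bend_angle
        p_end <- c(l1 + spec$bend_radius * sin(phi),
                   spec$bend_radius * (1 - cos(phi)), 0)
        t_end <- c(cos(phi), sin(phi), 0)
        pos[i, ] <- p_end + (si - l1 - arc) * t_end
        tan[i, ] <- t_end
      }
    }
  }
  binorm <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  norm <- row_cross(binorm, tan)
  norm <- norm / sqrt(rowSums(norm^2))
  list(positions = pos, tangents = tan, normals = norm, binormals = binorm,
       total_length = total)
}

tube_total_length <- function(spec) {
  if (!spec$curved) return(spec$length)
  spec$entry_length + spec$bend_radius * spec$bend_angle + spec$exit_length
}

#' Generate a tube phantom mesh
#'
#' Sweeps a circle of the given radius along the tube centerline (straight
#' line, or straight/arc/straight for a curved spec), producing a triangulated
#' surface with `circumferential_resolution x (axial_resolution + 1)` ring
#' vertices. Normals are oriented analytically toward the centerline. With
#' `capped_end = TRUE` the far end is closed by a fan whose inward direction
#' is the reversed end tangent.
#'
#' @param spec a [tube_spec()].
#' @return a [vessel_mesh()].
#' @export
make_tube <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  nc <- spec$circumferential_resolution
  na <- spec$axial_resolution
  cl <- tube_centerline(spec, seq(0, 1, length.out = na + 1L))
  # half-facet angular offset: facet centers (not vertex seams) face the
  # bend plane, so nodes moving in that plane project into a facet
  theta <- 2 * pi * (seq_len(nc) - 0.5) / nc
  nverts <- nc * (na + 1L)
  vertices <- matrix(0, nverts, 3)
  for (k in seq_len(na + 1L)) {
    ring <- cl$positions[rep(k, nc), ] +
      spec$radius * (outer(cos(theta), cl$normals[k, ]) +
                     outer(sin(theta), cl$binormals[k, ]))
    vertices[((k - 1L) * nc + 1L):(k * nc), ] <- ring
  }
  # side quads -> two triangles each
  tris <- matrix(0L, 2L * nc * na, 3L)
  row <- 1L
  for (k in seq_len(na)) {
    base0 <- (k - 1L) * nc
    base1 <- k * nc
    for (j in seq_len(nc)) {
      jn <- if (j == nc) 1L else j + 1L
      a <- base0 + j; b <- base0 + jn; cidx <- base1 + j; d <- base1 + jn
      tris[row, ] <- c(a, b, cidx); row <- row + 1L
      tris[row, ] <- c(b, d, cidx); row <- row + 1L
    }
  }
  normals <- orient_tube_normals(vertices, tris, cl)
  if (spec$capped_end) {
    centre_idx <- nrow(vertices) + 1L
    vertices <- rbind(vertices, cl$positions[na + 1L, ])
    base1 <- na * nc
    cap <- matrix(0L, nc, 3L)
    for (j in seq_len(nc)) {
      jn <- if (j == nc) 1L else j + 1L
      cap[j, ] <- c(base1 + j, base1 + jn, centre_idx)
    }
    tris <- rbind(tris, cap)
    cap_n <- matrix(rep(-cl$tangents[na + 1L, ], each = nc), nc, 3)
    normals <- rbind(normals, cap_n)
  }
  vessel_mesh(vertices, tris, normals = normals)
}

# Orient side-wall normals toward the nearest centerline point.
orient_tube_normals <- function(vertices, tris, cl) {
  normals <- winding_normals(vertices, tris)
  cent <- (vertices[tris[, 1L], , drop = FALSE] +
           vertices[tris[, 2L], , drop = FALSE] +
           vertices[tris[, 3L], , drop = FALSE]) / 3
  for (i in seq_len(nrow(tris))) {
    d2 <- rowSums(sweep(cl$positions, 2, cent[i, ])^2)
    target <- cl$positions[which.min(d2), ]
    if (sum(normals[i, ] * (target - cent[i, ])) < 0) {
      normals[i, ] <- -normals[i, ]
    }
  }
  normals
}
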