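#' A single node-triangle contact
#'
#' Records one active contact between a catheter node (index >= 1; the base
#' node is boundary-fixed and never contacts) and a vessel triangle, with the
#' triangle's inward plane `(n, d)` and the penetration depth
#' `p = max(0, -(n . x + d))` at detection time.
#'
#' @param node catheter node index (1-based over non-base nodes).
#' @param triangle mesh triangle index.
#' @param normal inward unit normal of the triangle plane.
#' @param offset plane offset `d`.
#' @param penetration penetration depth in mm, >= 0.
#' @return object of class `contact`.
#' @export
contact <- function(node, triangle, normal, offset, penetration) {
  node <- as.integer(node)
  if (node < 1L) stop("contact node index must be >= 1 (base node is fixed)",
                      call. = FALSE)
  if (penetration < 0) stop("penetration must be >= 0", call. = FALSE)
  structure(list(node = node, triangle = as.integer(triangle),
                 normal = as.numeric(normal), offset = as.numeric(offset),
                 penetration = as.numeric(penetration)),
            class = "contact")
}

#' Set of active contacts
#'
#' At most one contact per (node, triangle) pair; contacts are kept sorted
#' lexicographically by (node, triangle), so detection is deterministic.
#'
#' @param contacts list of [contact()] objects.
#' @return object of class `contact_set`.
#' @export
contact_set <- function(contacts = list()) {
  if (length(contacts) > 0L) {
    keys <- vapply(contacts, function(ct) ct$node * 1e9 + ct$triangle,
                   numeric(1))
    if (anyDuplicated(keys)) {
      stop("duplicate (node, triangle) contact", call. = FALSE)
    }
    contacts <- contacts[order(keys)]
  }
  structure(list(contacts = contacts), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("contact_set: %d active contact(s)\n", length(x$contacts)))
  invisible(x)
}

#' @export
length.contact_set <- function(x) length(x$contacts)

contact_keys <- function(cs) {
  if (length(cs$contacts) == 0L) return(character(0))
  vapply(cs$contacts, function(ct) paste(ct$node, ct$triangle), character(1))
}

#' Detect node-versus-wall contacts
#'
#' A node (index >= 1) contacts a triangle when (a) its signed distance to
#' the triangle's inward plane is below `margin` (at or beyond the wall) and
#' (b) its orthogonal projection onto the plane falls inside the triangle
#' (barycentric test with edge tolerance 1e-9). Candidates deeper than
#' `reach` beyond the plane are ignored, which bounds the search region for
#' the grid broad phase; the default `Inf` considers every pair.
#'
#' @param mesh a [vessel_mesh()].
#' @param positions N x 3 matrix of node positions (row 1 = base, never
#'   tested).
#' @param margin detection margin in mm, >= 0.
#' @param method `"brute"` (vectorized all-pairs, the reference) or `"grid"`
#'   (AABB-grid broad phase; requires finite `reach`). Both return identical
#'   sets for the same `reach`.
#' @param reach maximum penetration depth considered (mm).
#' @return a [contact_set()], sorted by (node, triangle).
#' @export
detect_contacts <- function(mesh, positions, margin = 0,
                            method = c("brute", "grid"), reach = Inf) {
  method <- match.arg(method)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  if (method == "grid" && !is.finite(reach)) {
    stop("grid broad phase needs a finite reach", call. = FALSE)
  }
  if (is.null(positions) || nrow(positions) < 2L) return(contact_set())
  pts <- positions[-1L, , drop = FALSE]     # base node excluded
  if (method == "grid") {
    cand <- grid_candidates(mesh, pts, margin + reach)
  } else {
    nn <- nrow(pts)
    mt <- nrow(mesh$triangles)
    cand <- cbind(node = rep(seq_len(nn), each = mt),
                  tri = rep(seq_len(mt), times = nn))
  }
  if (nrow(cand) == 0L) return(contact_set())
  contacts <- narrow_phase(mesh, pts, cand, margin, reach)
  contact_set(contacts)
}

# Exact per-candidate test: plane distance window + in-triangle projection.
narrow_phase <- function(mesh, pts, cand, margin, reach) {
  p <- pts[cand[, 1L], , drop = FALSE]
  n <- mesh$normals[cand[, 2L], , drop = FALSE]
  d <- mesh$offsets[cand[, 2L]]
  sd <- rowSums(n * p) + d
  keep <- sd <= margin & sd >= -reach
  if (!any(keep)) return(list())
  cand <- cand[keep, , drop = FALSE]
  p <- p[keep, , drop = FALSE]
  n <- n[keep, , drop = FALSE]
  d <- d[keep]
  sd <- sd[keep]
  # project onto the plane, then barycentric inside test
  proj <- p - sd * n
  tris <- mesh$triangles[cand[, 2L], , drop = FALSE]
  a <- mesh$vertices[tris[, 1L], , drop = FALSE]
  b <- mesh$vertices[tris[, 2L], , drop = FALSE]
  cc <- mesh$vertices[tris[, 3L], , drop = FALSE]
  v0 <- b - a; v1 <- cc - a; v2 <- proj - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  tol <- 1e-9
  inside <- u >= -tol & v >= -tol & w >= -tol
  idx <- which(inside)
  lapply(idx, function(k) {
    contact(cand[k, 1L], cand[k, 2L], n[k, ], d[k], max(0, -sd[k]))
  })
}

# Uniform-grid broad phase: triangles binned by AABB expanded by `pad`;
# each node queries its own cell.
grid_candidates <- function(mesh, pts, pad) {
  tris <- mesh$triangles
  lo <- pmin(mesh$vertices[tris[, 1L], , drop = FALSE],
             mesh$vertices[tris[, 2L], , drop = FALSE],
             mesh$vertices[tris[, 3L], , drop = FALSE]) - pad
  hi <- pmax(mesh$vertices[tris[, 1L], , drop = FALSE],
             mesh$vertices[tris[, 2L], , drop = FALSE],
             mesh$vertices[tris[, 3L], , drop = FALSE]) + pad
  dom_lo <- apply(lo, 2, min)
  dom_hi <- apply(hi, 2, max)
  cell <- max(dom_hi - dom_lo) / 16
  if (cell <= 0) cell <- 1
  key3 <- function(m) {
    ix <- pmax(0L, pmin(63L, as.integer(floor((m[, 1] - dom_lo[1]) / cell))))
    iy <- pmax(0L, pmin(63L, as.integer(floor((m[, 2] - dom_lo[2]) / cell))))
    iz <- pmax(0L, pmin(63L, as.integer(floor((m[, 3] - dom_lo[3]) / cell))))
    list(ix = ix, iy = iy, iz = iz)
  }
  klo <- key3(lo); khi <- key3(hi)
  buckets <- new.env(parent = emptyenv(), hash = TRUE)
  for (t in seq_len(nrow(tris))) {
    for (ix in klo$ix[t]:khi$ix[t]) for (iy in klo$iy[t]:khi$iy[t])
      for (iz in klo$iz[t]:khi$iz[t]) {
        k <- paste(ix, iy, iz)
        buckets[[k]] <- c(buckets[[k]], t)
      }
  }
  kp <- key3(pts)
  out_node <- integer(0); out_tri <- integer(0)
  for (i in seq_len(nrow(pts))) {
    k <- paste(kp$ix[i], kp$iy[i], kp$iz[i])
    ts <- buckets[[k]]
    if (!is.null(ts)) {
      out_node <- c(out_node, rep.int(i, length(ts)))
      out_tri <- c(out_tri, ts)
    }
  }
  cbind(node = out_node, tri = out_tri)
}

#' Maximum wall penetration of a catheter configuration
#'
#' Largest penetration depth over all nodes against the mesh (0 when every
#' node is inside the lumen). A diagnostic for how well the penalty
#' stiffness resolves contact.
#'
#' @param mesh a [vessel_mesh()].
#' @param positions N x 3 matrix of node positions.
#' @return scalar mm >= 0.
#' @export
max_penetration <- function(mesh, positions) {
  cs <- detect_contacts(mesh, positions, margin = 0)
  if (length(cs$contacts) == 0L) return(0)
  max(vapply(cs$contacts, function(ct) ct$penetration, numeric(1)))
}
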