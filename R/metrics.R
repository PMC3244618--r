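#' Resample a polyline uniformly by arc length
#'
#' Linear interpolation along the polyline, starting at its first point, with
#' consecutive samples separated by `spacing` measured along the curve. The
#' sample count is `floor(total length / spacing) + 1`.
#'
#' @param points matrix (>= 2 rows) of 3D points.
#' @param spacing arc-length spacing in mm, > 0 and <= total length.
#' @return matrix of resampled points.
#' @export
resample_polyline <- function(points, spacing) {
  points <- as_xyz_matrix(points, "points")
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (spacing > total) {
    stop("spacing exceeds the polyline's total length", call. = FALSE)
  }
  s <- seq(0, by = spacing, length.out = floor(total / spacing + 1e-9) + 1L)
  out <- matrix(0, length(s), 3L)
  for (k in seq_along(s)) {
    i <- findInterval(s[k], cum, rightmost.closed = TRUE)
    if (i >= length(cum)) i <- length(cum) - 1L
    f <- if (seg[i] > 0) (s[k] - cum[i]) / seg[i] else 0
    out[k, ] <- (1 - f) * points[i, ] + f * points[i + 1L, ]
  }
  out
}

#' Compare two discretized curves node by node
#'
#' Per-node Euclidean distances between a simulated curve and a reference
#' curve with matched node counts (the reference is expected to be
#' pre-resampled at the simulation's segment length), summarized as their
#' root mean square and maximum:
#' `RMS = sqrt( (1/n) sum_i dist_i^2 )`, `dist_i = ||x_i_sim - x_i_ref||`.
#'
#' @param sim,ref matrices of 3D points with equal row counts.
#' @return object of class `curve_comparison` with fields `rms`,
#'   `max_displacement`, `per_node_distances`, `n`.
#' @export
compare_curves <- function(sim, ref) {
  sim <- as_xyz_matrix(sim, "sim")
  ref <- as_xyz_matrix(ref, "ref")
  if (nrow(sim) != nrow(ref)) {
    stop("curves must have the same number of points", call. = FALSE)
  }
  d <- sqrt(rowSums((sim - ref)^2))
  structure(list(rms = sqrt(mean(d^2)), max_displacement = max(d),
                 per_node_distances = d, n = length(d)),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("curve_comparison over %d nodes: RMS %.4g mm, max %.4g mm\n",
              x$n, x$rms, x$max_displacement))
  invisible(x)
}
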