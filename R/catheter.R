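#' Discrete catheter state in tangent space
#'
#' The catheter centerline is discretized into `N` nodes and `N - 1` elements.
#' The solver's unknowns are the nodal tangent vectors `t_1 ... t_{N-1}`; the
#' base tangent `t_0` is the sheath boundary condition and stays fixed, and
#' node positions are recovered by trapezoid integration of the piecewise-
#' linear tangent field (exact for that interpolant). All elements have the
#' nominal segment length `l` except possibly the base element, which absorbs
#' partial insertion so that push/pull steps smaller than `l` are supported.
#'
#' Tangents other than `t_0` are not constrained to unit norm: the linear
#' equilibrium solve cannot enforce the constraint, and no renormalization is
#' applied (it would change the minimizer). The drift `max_i | ||t_i|| - 1 |`
#' is reported as a per-step diagnostic instead.
#'
#' @param base_position numeric 3-vector, sheath exit position (mm).
#' @param base_tangent unit 3-vector, sheath direction (boundary condition).
#' @param tangents (N-1) x 3 matrix of nodal tangents `t_1 ... t_{N-1}`.
#' @param element_lengths numeric vector of N-1 element lengths (mm); element
#'   1 is the base element and is the only one allowed to be shorter than the
#'   nominal segment length.
#' @param segment_length nominal segment length `l` (mm).
#' @return an object of class `catheter_state` (positions are reconstructed
#'   and cached).
#' @export
catheter_state <- function(base_position, base_tangent, tangents,
                           element_lengths, segment_length) {
  base_position <- as.numeric(base_position)
  base_tangent <- as.numeric(base_tangent)
  stopifnot(length(base_position) == 3L, length(base_tangent) == 3L)
  if (abs(sqrt(sum(base_tangent^2)) - 1) > 1e-12) {
    stop("base_tangent must be a unit vector", call. = FALSE)
  }
  tangents <- as_xyz_matrix(tangents, "tangents")
  element_lengths <- as.numeric(element_lengths)
  if (nrow(tangents) != length(element_lengths)) {
    stop("need one tangent per element", call. = FALSE)
  }
  if (length(element_lengths) < 1L) stop("need at least one element", call. = FALSE)
  l <- segment_length
  if (!is.numeric(l) || l <= 0) stop("segment_length must be > 0", call. = FALSE)
  if (any(element_lengths <= 0) || any(element_lengths > l + 1e-9)) {
    stop("element lengths must lie in (0, segment_length]", call. = FALSE)
  }
  if (any(abs(element_lengths[-1L] - l) > 1e-9)) {
    stop("only the base element may differ from segment_length", call. = FALSE)
  }
  st <- structure(
    list(base_position = base_position, base_tangent = base_tangent,
         tangents = tangents, element_lengths = element_lengths,
         segment_length = l, positions = NULL),
    class = "catheter_state")
  st$positions <- reconstruct_positions(st)
  st
}

#' @export
print.catheter_state <- function(x, ...) {
  n <- n_nodes(x)
  tip <- x$positions[n, ]
  cat(sprintf("catheter_state: %d nodes, %d elements, length %.4g mm (l = %.4g mm)\n",
              n, n - 1L, inserted_length(x), x$segment_length))
  cat(sprintf("  base (%.3g, %.3g, %.3g)  tip (%.3g, %.3g, %.3g)\n",
              x$base_position[1], x$base_position[2], x$base_position[3],
              tip[1], tip[2], tip[3]))
  invisible(x)
}

#' Number of catheter nodes (including the base)
#' @param state a [catheter_state()].
#' @return integer N.
#' @export
n_nodes <- function(state) nrow(state$tangents) + 1L

#' Total inserted arc length of a catheter state
#' @param state a [catheter_state()].
#' @return scalar mm.
#' @export
inserted_length <- function(state) sum(state$element_lengths)

#' Initialize a straight catheter
#'
#' Builds a catheter lying along the sheath direction: every tangent equals
#' `base_tangent`, so the bending energy is exactly zero. The element count is
#' `ceiling(initial_length / segment_length)`; when `initial_length` is not a
#' multiple of `segment_length` the base element takes the remainder.
#'
#' @param base_position numeric 3-vector (mm).
#' @param base_tangent unit 3-vector.
#' @param initial_length total inserted length, >= `segment_length` (mm).
#' @param segment_length nominal element length `l` (mm).
#' @return list with `state` (a [catheter_state()]) and `insertion`
#'   (an [insertion_state()]).
#' @export
init_catheter <- function(base_position, base_tangent, initial_length,
                          segment_length) {
  l <- segment_length
  if (initial_length < l - 1e-12) {
    stop("initial_length must be >= segment_length", call. = FALSE)
  }
  n_el <- as.integer(ceiling(initial_length / l - 1e-12))
  base_el <- initial_length - (n_el - 1L) * l
  h <- c(base_el, rep(l, n_el - 1L))
  tangents <- matrix(rep(base_tangent, each = n_el), n_el, 3L)
  state <- catheter_state(base_position, base_tangent, tangents, h, l)
  list(state = state, insertion = insertion_state(initial_length, l))
}

#' Insertion bookkeeping
#'
#' Tracks the total inserted length and the partial advance held in the base
#' element; `residual` is `inserted_length mod l` (0 when the base element is
#' full).
#'
#' @param inserted_length total arc length (mm), >= segment length.
#' @param segment_length nominal element length (mm).
#' @return object of class `insertion_state`.
#' @export
insertion_state <- function(inserted_length, segment_length) {
  res <- inserted_length %% segment_length
  if (res > segment_length - 1e-12 || res < 1e-12) res <- 0
  structure(list(inserted_length = inserted_length, residual = res),
            class = "insertion_state")
}

#' Reconstruct node positions from tangents
#'
#' Integrates the piecewise-linear tangent field by the trapezoid rule, which
#' is exact for that interpolant:
#' `x_i = x_{i-1} + (h_i / 2) (t_{i-1} + t_i)`.
#'
#' @param state a [catheter_state()].
#' @return N x 3 matrix of node positions (row 1 is the base).
#' @export
reconstruct_positions <- function(state) {
  tall <- rbind(state$base_tangent, state$tangents)
  h <- state$element_lengths
  n_el <- length(h)
  steps <- (h / 2) * (tall[seq_len(n_el), , drop = FALSE] +
                      tall[seq_len(n_el) + 1L, , drop = FALSE])
  pos <- apply(steps, 2L, cumsum)
  if (n_el == 1L) pos <- matrix(pos, 1L, 3L)
  pos <- sweep(pos, 2L, state$base_position, "+")
  rbind(state$base_position, pos)
}

#' Affine map from stacked tangents to stacked positions
#'
#' Builds the lower-block-triangular matrix `B` and offset `c` such that the
#' stacked non-base positions satisfy `(x_1, ..., x_{N-1}) = B t + c` where
#' `t` stacks the unknown tangents `t_1 ... t_{N-1}` (x, y, z interleaved per
#' node). The diagonal blocks are `(h_i / 2) I_3`, so `B` is nonsingular with
#' determinant `prod(h_i / 2)^3`.
#'
#' @param state a [catheter_state()].
#' @return list with `B` (3(N-1) x 3(N-1) matrix) and `c` (3(N-1) vector).
#' @export
assemble_B <- function(state) {
  h <- state$element_lengths
  m <- length(h)
  # coefficient of t_k in x_i: h_k/2 + h_{k+1}/2 for k < i, h_i/2 for k = i
  coef <- matrix(0, m, m)
  for (i in seq_len(m)) {
    if (i > 1L) {
      ks <- seq_len(i - 1L)
      coef[i, ks] <- h[ks] / 2 + h[ks + 1L] / 2
    }
    coef[i, i] <- h[i] / 2
  }
  B <- kronecker(coef, diag(3))
  c0 <- rep(state$base_position + (h[1L] / 2) * state$base_tangent, m)
  list(B = B, c = c0)
}

#' Push the catheter in at the sheath
#'
#' Grows the base element by `h`; when it would exceed the nominal segment
#' length a new node is inserted at the base with the sheath tangent `t_0`
#' and the base element wraps around. All other tangents are preserved, so
#' total arc length increases by exactly `h`.
#'
#' @param state a [catheter_state()].
#' @param insertion an [insertion_state()].
#' @param h step size in mm, 0 < h <= segment length.
#' @return list with updated `state` and `insertion`.
#' @export
advance_catheter <- function(state, insertion, h) {
  l <- state$segment_length
  if (h <= 0 || h > l + 1e-12) stop("step must lie in (0, l]", call. = FALSE)
  base_el <- state$element_lengths[1L]
  if (base_el + h > l + 1e-12) {
    # base element wraps: insert a fresh node at the sheath with tangent t0
    new_base <- base_el + h - l
    tangents <- rbind(state$base_tangent, state$tangents)
    el <- c(new_base, l, state$element_lengths[-1L])
  } else {
    tangents <- state$tangents
    el <- state$element_lengths
    el[1L] <- base_el + h
  }
  st <- catheter_state(state$base_position, state$base_tangent, tangents, el,
                       l)
  list(state = st,
       insertion = insertion_state(insertion$inserted_length + h, l))
}

#' Pull the catheter out at the sheath
#'
#' Mirror of [advance_catheter()]: the base element shrinks by `h`; when it
#' would vanish the base node is removed and the next element becomes the
#' (partial) base element. The catheter may not be withdrawn past one
#' element.
#'
#' @inheritParams advance_catheter
#' @return list with updated `state` and `insertion`.
#' @export
retract_catheter <- function(state, insertion, h) {
  l <- state$segment_length
  if (h <= 0 || h > l + 1e-12) stop("step must lie in (0, l]", call. = FALSE)
  if (insertion$inserted_length - h < l - 1e-9) {
    stop("cannot withdraw past one element", call. = FALSE)
  }
  base_el <- state$element_lengths[1L]
  if (base_el - h > 1e-12) {
    tangents <- state$tangents
    el <- state$element_lengths
    el[1L] <- base_el - h
  } else {
    # base element consumed: drop the base node
    new_base <- base_el - h + l
    if (abs(new_base - l) < 1e-12) new_base <- l
    tangents <- state$tangents[-1L, , drop = FALSE]
    el <- c(new_base, state$element_lengths[-(1:2)])
  }
  st <- catheter_state(state$base_position, state$base_tangent, tangents, el,
                       l)
  list(state = st,
       insertion = insertion_state(insertion$inserted_length - h, l))
}
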