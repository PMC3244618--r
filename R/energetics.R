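#' Quadratic form over the stacked unknown tangents
#'
#' Every term of the total potential
#' `Pi = U_e + U_p - W` is quadratic in the stacked unknown tangents
#' `t = (t_1, ..., t_{N-1})` and is stored as
#' `E(t) = 1/2 t' H t + g' t + c` with `H` symmetric. Forms over the same
#' unknowns add componentwise (`+`), and the stationarity system of the sum
#' is `(sum H) t = -(sum g)`.
#'
#' @param H symmetric matrix (symmetrized on construction), or a scalar 0 for
#'   the zero matrix of dimension `d`.
#' @param g numeric vector.
#' @param c scalar constant.
#' @param d dimension, required when `H` is given as 0.
#' @return object of class `quadratic_form`.
#' @export
quadratic_form <- function(H, g, c = 0, d = NULL) {
  if (is.null(dim(H))) {
    if (!identical(as.numeric(H), 0)) stop("scalar H must be 0", call. = FALSE)
    if (is.null(d)) d <- length(g)
    H <- matrix(0, d, d)
  }
  H <- (H + t(H)) / 2
  g <- as.numeric(g)
  if (length(g) != nrow(H)) stop("dimension mismatch in quadratic form",
                                 call. = FALSE)
  structure(list(H = H, g = g, c = as.numeric(c)), class = "quadratic_form")
}

#' @export
`+.quadratic_form` <- function(e1, e2) {
  if (nrow(e1$H) != nrow(e2$H)) stop("dimension mismatch", call. = FALSE)
  quadratic_form(e1$H + e2$H, e1$g + e2$g, e1$c + e2$c)
}

#' @export
print.quadratic_form <- function(x, ...) {
  cat(sprintf("quadratic_form over %d unknowns (|H|_max %.3g, |g|_max %.3g, c %.6g)\n",
              length(x$g), max(abs(x$H)), max(abs(x$g)), x$c))
  invisible(x)
}

#' Evaluate a quadratic form
#' @param form a [quadratic_form()].
#' @param t stacked tangent vector.
#' @return scalar energy.
#' @export
eval_form <- function(form, t) {
  t <- as.numeric(t)
  if (length(t) != length(form$g)) stop("dimension mismatch", call. = FALSE)
  0.5 * sum(t * (form$H %*% t)) + sum(form$g * t) + form$c
}

#' Material parameters of the catheter/vessel system
#'
#' @param alpha bending constant of the Kirchhoff rod energy (energy x mm);
#'   must be > 0 so the elastic form is positive-definite over the unknowns.
#' @param kappa elastic modulus of the vessel wall for the penetration
#'   penalty (energy / mm^2); >= 0.
#' @return object of class `material_params`.
#' @export
material_params <- function(alpha = 1, kappa = 100) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, kappa = kappa), class = "material_params")
}

#' External nodal loads
#'
#' User-applied forces on catheter nodes; the work term is
#' `W = sum_i f_i . (x_i - x_i0)` with `x_i0` the node's position at the last
#' equilibrium.
#'
#' @param forces named list or NULL: names are node indices (1-based,
#'   excluding the base node 0-equivalent row 1), values numeric 3-vectors.
#' @param reference_positions N x 3 matrix of positions at the previous
#'   equilibrium (row 1 = base).
#' @return object of class `external_load`.
#' @export
external_load <- function(forces = NULL, reference_positions = NULL) {
  if (!is.null(forces)) {
    if (is.null(names(forces)) || any(names(forces) == "")) {
      stop("forces must be a named list (names = node indices)", call. = FALSE)
    }
    idx <- as.integer(names(forces))
    if (anyNA(idx) || any(idx < 1L)) {
      stop("force node indices must be >= 1 (base node carries no load DoF)",
           call. = FALSE)
    }
  }
  structure(list(forces = forces, reference_positions = reference_positions),
            class = "external_load")
}

#' Bending energy as a quadratic form
#'
#' The discretized Kirchhoff bending energy of the piecewise-linear tangent
#' field is `U_e = alpha * sum_i ||t_i - t_{i-1}||^2 / h_i` over elements
#' `i = 1 ... N-1` with per-element lengths `h_i`. The fixed boundary tangent
#' `t_0` folds into the linear and constant parts.
#'
#' @param state a [catheter_state()].
#' @param params a [material_params()].
#' @return a [quadratic_form()] over the 3(N-1) unknowns.
#' @export
elastic_quadratic <- function(state, params) {
  h <- state$element_lengths
  m <- length(h)
  a <- params$alpha
  w <- 2 * a / h            # element stiffness 2 alpha / h_i
  coef <- matrix(0, m, m)
  for (i in seq_len(m)) {
    coef[i, i] <- w[i] + if (i < m) w[i + 1L] else 0
    if (i < m) {
      coef[i, i + 1L] <- -w[i + 1L]
      coef[i + 1L, i] <- -w[i + 1L]
    }
  }
  H <- kronecker(coef, diag(3))
  g <- numeric(3L * m)
  g[1:3] <- -w[1L] * state$base_tangent
  cc <- (a / h[1L]) * sum(state$base_tangent^2)
  quadratic_form(H, g, cc)
}

#' Wall-penalty energy as a quadratic form
#'
#' Each active contact `j` of node `x_j` with a vessel triangle of inward
#' plane `(n_j, d_j)` contributes `1/2 kappa (n_j . x_j + d_j)^2` (Hooke's
#' law on the penetration depth). Substituting the affine position map
#' `x = B t + c` makes the penalty quadratic in the unknown tangents.
#' Contacts on the base node are rejected with a warning: the base is the
#' boundary condition, not a degree of freedom.
#'
#' @param state a [catheter_state()].
#' @param contacts a [contact_set()].
#' @param params a [material_params()].
#' @param B,c position map from [assemble_B()].
#' @return a [quadratic_form()].
#' @export
contact_quadratic <- function(state, contacts, params, B, c) {
  m <- nrow(state$tangents)
  d <- 3L * m
  if (length(contacts$contacts) == 0L) {
    return(quadratic_form(0, numeric(d), 0, d = d))
  }
  kap <- params$kappa
  rows <- list()
  svals <- numeric(0)
  for (ct in contacts$contacts) {
    if (ct$node < 1L) {
      warning("contact on the fixed base node ignored (boundary contact)",
              call. = FALSE)
      next
    }
    if (ct$node > m) stop("contact node index out of range", call. = FALSE)
    blk <- (3L * ct$node - 2L):(3L * ct$node)
    q <- as.numeric(ct$normal %*% B[blk, , drop = FALSE])
    s <- sum(ct$normal * c[blk]) + ct$offset
    rows[[length(rows) + 1L]] <- q
    svals <- c(svals, s)
  }
  if (length(rows) == 0L) return(quadratic_form(0, numeric(d), 0, d = d))
  Q <- do.call(rbind, rows)
  H <- kap * crossprod(Q)
  g <- kap * as.numeric(crossprod(Q, svals))
  cc <- 0.5 * kap * sum(svals^2)
  quadratic_form(H, g, cc)
}

#' Work of external forces as a (linear) quadratic form
#'
#' Represents the negative work `-W = -sum_i f_i . (x_i - x_i0)` under the
#' standard minimal-total-potential convention `Pi = U_e + U_p - W`, with
#' positions substituted via the affine map `x = B t + c`. Setting
#' `sign_convention = "paper_literal"` flips the sign (adds `+W` to the
#' objective instead).
#'
#' @param state a [catheter_state()].
#' @param load an [external_load()].
#' @param B,c position map from [assemble_B()].
#' @param sign_convention `"standard"` (default) or `"paper_literal"`.
#' @return a [quadratic_form()] with `H = 0`.
#' @export
external_work_quadratic <- function(state, load, B, c,
                                    sign_convention = c("standard",
                                                        "paper_literal")) {
  sign_convention <- match.arg(sign_convention)
  m <- nrow(state$tangents)
  d <- 3L * m
  g <- numeric(d)
  cc <- 0
  if (!is.null(load$forces) && length(load$forces) > 0L) {
    ref <- load$reference_positions
    if (is.null(ref)) ref <- state$positions
    for (nm in names(load$forces)) {
      i <- as.integer(nm)
      if (i > m) stop("force node index out of range", call. = FALSE)
      f <- as.numeric(load$forces[[nm]])
      blk <- (3L * i - 2L):(3L * i)
      # -W contribution: -(f' B_i) t - f . (c_i - x_i0)
      g <- g - as.numeric(crossprod(B[blk, , drop = FALSE], f))
      cc <- cc - sum(f * (c[blk] - ref[i + 1L, ]))
    }
  }
  if (sign_convention == "paper_literal") {
    g <- -g
    cc <- -cc
  }
  quadratic_form(0, g, cc, d = d)
}

#' Total potential energy at a tangent configuration
#'
#' Sums the evaluations of the given quadratic forms at `t`.
#'
#' @param forms list of [quadratic_form()] objects over the same unknowns.
#' @param t stacked tangent vector.
#' @return scalar.
#' @export
total_potential <- function(forms, t) {
  sum(vapply(forms, eval_form, numeric(1), t = t))
}
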