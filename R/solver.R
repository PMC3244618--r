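#' Solver configuration
#'
#' Controls the active-set contact loop around the linear equilibrium solve.
#' Each outer iteration re-detects contacts from the current positions,
#' rebuilds the energy forms, solves the stationarity system and
#' reconstructs positions; convergence means the active set repeated and the
#' maximum penetration changed by less than `active_set_tolerance`. Setting
#' `max_outer_iterations = 1` reproduces a single detect-then-solve pass.
#'
#' @param max_outer_iterations cap on active-set iterations, >= 1.
#' @param active_set_tolerance penetration-change threshold in mm, > 0.
#' @param linear_solver only `"direct"` (dense Cholesky) is provided; the
#'   system is small (3(N-1) unknowns).
#' @param sign_convention `"standard"` minimizes `U_e + U_p - W`;
#'   `"paper_literal"` uses `U_e + U_p + W`.
#' @param margin contact-detection margin in mm. A small positive retention
#'   band keeps resting contacts (nodes the penalty has pushed back to the
#'   wall plane, signed distance near 0) in the active set between
#'   iterations; with a margin of exactly 0 such contacts are released the
#'   moment they stop penetrating and the active set can oscillate between
#'   the free and the constrained shape.
#' @param collision_method `"brute"` or `"grid"` (see [detect_contacts()]).
#' @param collision_reach penetration cutoff for the grid broad phase (mm).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(max_outer_iterations = 50L,
                          active_set_tolerance = 1e-6,
                          linear_solver = "direct",
                          sign_convention = c("standard", "paper_literal"),
                          margin = 0.05,
                          collision_method = c("brute", "grid"),
                          collision_reach = Inf) {
  max_outer_iterations <- as.integer(max_outer_iterations)
  if (max_outer_iterations < 1L) {
    stop("max_outer_iterations must be >= 1", call. = FALSE)
  }
  if (active_set_tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  linear_solver <- match.arg(linear_solver, "direct")
  structure(
    list(max_outer_iterations = max_outer_iterations,
         active_set_tolerance = active_set_tolerance,
         linear_solver = linear_solver,
         sign_convention = match.arg(sign_convention),
         margin = margin,
         collision_method = match.arg(collision_method),
         collision_reach = collision_reach),
    class = "solver_config")
}

#' Assemble the stationarity system of a sum of quadratic forms
#'
#' For the total potential `Pi(t) = sum_k (1/2 t' H_k t + g_k' t + c_k)` the
#' stationarity condition `grad Pi = 0` reads `A t = b` with `A = sum H_k`
#' and `b = -sum g_k`. `A` is symmetric positive-definite whenever the
#' bending constant is positive (the elastic form restricted to the unknowns
#' is positive-definite with `t_0` fixed, and the penalty forms are positive
#' semidefinite).
#'
#' @param forms list of [quadratic_form()] objects over the same unknowns.
#' @return list with matrix `A` and vector `b`.
#' @export
assemble_system <- function(forms) {
  stopifnot(length(forms) >= 1L)
  d <- length(forms[[1L]]$g)
  A <- matrix(0, d, d)
  b <- numeric(d)
  for (f in forms) {
    if (length(f$g) != d) stop("dimension mismatch across forms", call. = FALSE)
    A <- A + f$H
    b <- b - f$g
  }
  list(A = (A + t(A)) / 2, b = b)
}

#' Solve the symmetric positive-definite equilibrium system
#'
#' Dense Cholesky solve of `A t = b` in tangent space. This is algebraically
#' identical to composing with the position map (`A B^{-1} x = b`) since `B`
#' is nonsingular; solving for the tangents directly avoids inverting `B`.
#'
#' @param A symmetric positive-definite matrix.
#' @param b right-hand side.
#' @return solution vector `t` with `||A t - b|| <= 1e-10 (1 + ||b||)`.
#' @export
solve_linear <- function(A, b) {
  R <- tryCatch(chol(A), error = function(e) {
    ev <- eigen(A, symmetric = TRUE)
    k <- which.min(ev$values)
    stop(sprintf(
      "system matrix is not positive-definite (min eigenvalue %.3g along unknown %d)",
      ev$values[k], which.max(abs(ev$vectors[, k]))), call. = FALSE)
  })
  t_sol <- backsolve(R, forwardsolve(t(R), b))
  # one step of iterative refinement keeps the residual at round-off
  r <- b - A %*% t_sol
  t_sol <- t_sol + backsolve(R, forwardsolve(t(R), r))
  as.numeric(t_sol)
}

stacked_tangents <- function(state) as.numeric(t(state$tangents))

set_tangents <- function(state, tvec) {
  m <- nrow(state$tangents)
  state$tangents <- matrix(tvec, m, 3L, byrow = TRUE)
  state$positions <- reconstruct_positions(state)
  state
}

build_forms <- function(state, contacts, params, load, cfg, Bc = NULL) {
  if (is.null(Bc)) Bc <- assemble_B(state)
  list(elastic = elastic_quadratic(state, params),
       contact = contact_quadratic(state, contacts, params, Bc$B, Bc$c),
       work = external_work_quadratic(state, load, Bc$B, Bc$c,
                                      sign_convention = cfg$sign_convention))
}

#' Solve for the catheter's equilibrium shape
#'
#' Finds the minimizer of the total potential (bending + wall penalty -
#' external work) for the current inserted length, by iterating contact
#' detection and the linear stationarity solve until the active contact set
#' is stable (see [solver_config()]). Non-convergence within the iteration
#' cap is reported in the result, never raised.
#'
#' @param state a [catheter_state()].
#' @param mesh a [vessel_mesh()], or NULL for free space.
#' @param params a [material_params()].
#' @param load an [external_load()] (default: no forces).
#' @param cfg a [solver_config()].
#' @return object of class `equilibrium_result` with fields `state`,
#'   `contacts`, `potential`, `energies` (U_e, U_p, W), `gradient_residual`,
#'   `outer_iterations`, `converged`, `tangent_norm_drift`,
#'   `max_penetration`.
#' @export
solve_equilibrium <- function(state, mesh = NULL, params = material_params(),
                              load = external_load(), cfg = solver_config()) {
  Bc <- assemble_B(state)
  detect <- function(st) {
    if (is.null(mesh)) return(contact_set())
    detect_contacts(mesh, st$positions, margin = cfg$margin,
                    method = cfg$collision_method,
                    reach = cfg$collision_reach)
  }
  set_pen <- function(cs) {
    if (length(cs$contacts) == 0L) 0 else
      max(vapply(cs$contacts, function(ct) ct$penetration, numeric(1)))
  }
  converged <- FALSE
  iter <- 0L
  sys <- NULL
  contacts <- detect(state)
  prev_pen <- set_pen(contacts)
  repeat {
    iter <- iter + 1L
    forms <- build_forms(state, contacts, params, load, cfg, Bc = Bc)
    sys <- assemble_system(unname(forms))
    tvec <- solve_linear(sys$A, sys$b)
    state <- set_tangents(state, tvec)
    new_contacts <- detect(state)
    pen <- set_pen(new_contacts)
    if (identical(contact_keys(new_contacts), contact_keys(contacts)) &&
        abs(pen - prev_pen) < cfg$active_set_tolerance) {
      contacts <- new_contacts
      converged <- TRUE
      break
    }
    if (iter >= cfg$max_outer_iterations) break
    contacts <- new_contacts
    prev_pen <- pen
  }
  tvec <- stacked_tangents(state)
  resid <- sqrt(sum((sys$A %*% tvec - sys$b)^2))
  forms <- build_forms(state, contacts, params, load, cfg, Bc = Bc)
  norms <- sqrt(rowSums(state$tangents^2))
  w_sign <- if (cfg$sign_convention == "standard") -1 else 1
  res <- list(
    state = state,
    contacts = contacts,
    potential = total_potential(unname(forms), tvec),
    energies = c(U_e = eval_form(forms$elastic, tvec),
                 U_p = eval_form(forms$contact, tvec),
                 W = w_sign * eval_form(forms$work, tvec)),
    gradient_residual = resid,
    outer_iterations = iter,
    converged = converged && resid <= 1e-8 * (1 + sqrt(sum(sys$b^2))),
    tangent_norm_drift = max(abs(norms - 1)),
    max_penetration = if (is.null(mesh)) 0 else
      max_penetration(mesh, state$positions),
    system = sys)
  class(res) <- "equilibrium_result"
  res
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "equilibrium_result: %s in %d iteration(s)\n",
    if (x$converged) "converged" else "NOT converged", x$outer_iterations))
  cat(sprintf("  Pi = %.6g (U_e %.4g, U_p %.4g, W %.4g)\n",
              x$potential, x$energies["U_e"], x$energies["U_p"],
              x$energies["W"]))
  cat(sprintf("  |At-b| = %.3g, contacts %d, max penetration %.4g mm, drift %.3g\n",
              x$gradient_residual, length(x$contacts$contacts),
              x$max_penetration, x$tangent_norm_drift))
  invisible(x)
}

#' Run a scripted push/pull sequence to quasi-static equilibria
#'
#' Applies each signed input step (positive = push, negative = pull) by
#' re-discretizing the catheter at the sheath and solving for the new
#' equilibrium. The work term's reference positions are the previous
#' equilibrium, matching the quasi-static model in which each input maps one
#' equilibrium to the next. Non-convergent steps are recorded in the trace,
#' not fatal.
#'
#' @param initial list with `state` and `insertion` (from [init_catheter()]).
#' @param mesh a [vessel_mesh()] or NULL.
#' @param params a [material_params()].
#' @param inputs numeric vector of signed steps in mm, each `|step| <= l`.
#' @param cfg a [solver_config()].
#' @param forces optional named list of per-node forces applied at every step
#'   (names = node indices).
#' @return object of class `simulation_trace`: list with `results` (one
#'   [solve_equilibrium()] result per row), `steps` (the inputs, 0 first for
#'   the initial state) and `table` (per-step diagnostics data frame).
#' @export
simulate_sequence <- function(initial, mesh = NULL,
                              params = material_params(), inputs = numeric(),
                              cfg = solver_config(), forces = NULL) {
  state <- initial$state
  insertion <- initial$insertion
  l <- state$segment_length
  if (length(inputs) > 0L && any(abs(inputs) > l + 1e-12)) {
    stop("every input step must satisfy |step| <= segment_length",
         call. = FALSE)
  }
  results <- vector("list", length(inputs) + 1L)
  ref_positions <- state$positions
  res <- solve_equilibrium(state, mesh, params,
                           external_load(forces, ref_positions), cfg)
  results[[1L]] <- res
  state <- res$state
  for (k in seq_along(inputs)) {
    ref_positions <- state$positions
    moved <- if (inputs[k] >= 0) {
      advance_catheter(state, insertion, inputs[k])
    } else {
      retract_catheter(state, insertion, -inputs[k])
    }
    state <- moved$state
    insertion <- moved$insertion
    # reference positions gain/lose a base row with the node count
    ref <- match_reference(ref_positions, n_nodes(state), state)
    res <- solve_equilibrium(state, mesh, params,
                             external_load(forces, ref), cfg)
    results[[k + 1L]] <- res
    state <- res$state
  }
  trace <- list(results = results, steps = c(0, inputs),
                insertion = insertion,
                table = trace_table(results, c(0, inputs)))
  class(trace) <- "simulation_trace"
  trace
}

# Align previous-equilibrium reference positions with a state whose node
# count changed at the base (new rows take the fresh node's position).
match_reference <- function(ref, n, state) {
  have <- nrow(ref)
  if (have == n) return(ref)
  if (have < n) {
    extra <- state$positions[seq_len(n - have) + 1L, , drop = FALSE]
    return(rbind(ref[1L, , drop = FALSE], extra, ref[-1L, , drop = FALSE]))
  }
  rbind(ref[1L, , drop = FALSE], ref[-seq_len(have - n + 1L), , drop = FALSE])
}

trace_table <- function(results, steps) {
  data.frame(
    step = seq_along(results) - 1L,
    input = steps,
    n_nodes = vapply(results, function(r) n_nodes(r$state), integer(1)),
    potential = vapply(results, function(r) r$potential, numeric(1)),
    U_e = vapply(results, function(r) unname(r$energies["U_e"]), numeric(1)),
    U_p = vapply(results, function(r) unname(r$energies["U_p"]), numeric(1)),
    W = vapply(results, function(r) unname(r$energies["W"]), numeric(1)),
    gradient_residual = vapply(results, function(r) r$gradient_residual,
                               numeric(1)),
    max_penetration = vapply(results, function(r) r$max_penetration,
                             numeric(1)),
    tangent_norm_drift = vapply(results, function(r) r$tangent_norm_drift,
                                numeric(1)),
    converged = vapply(results, function(r) r$converged, logical(1)),
    outer_iterations = vapply(results, function(r) r$outer_iterations,
                              integer(1)))
}

#' @export
print.simulation_trace <- function(x, ...) {
  n <- length(x$results)
  cat(sprintf("simulation_trace: %d state(s) (%d input step(s))\n", n, n - 1L))
  cat(sprintf("  converged %d/%d, final U_e %.4g, final max penetration %.4g mm\n",
              sum(x$table$converged), n, x$table$U_e[n],
              x$table$max_penetration[n]))
  invisible(x)
}
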