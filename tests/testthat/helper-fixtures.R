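# Shared fixtures and independent oracles for the test suite.

# The curved-tube phantom used by the contact scenarios: 10 mm entry,
# 90-degree bend of radius 15 mm, 20 mm exit, lumen radius 3 mm.
curved_tube_mesh <- function(circ = 16L, axial = 44L) {
  make_tube(tube_spec(radius = 3, bend_radius = 15, bend_angle = pi / 2,
                      entry_length = 10, exit_length = 20,
                      circumferential_resolution = circ,
                      axial_resolution = axial))
}

# Capped straight tube for the obstructed-tip scenario.
capped_tube_mesh <- function() {
  make_tube(tube_spec(radius = 5, length = 40,
                      circumferential_resolution = 16L,
                      axial_resolution = 30L, capped_end = TRUE))
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Term-by-term total potential: bending alpha*sum(||dt||^2/h), Hooke penalty
# per contact, minus external work, with positions from the trapezoid
# reconstruction. Independent of the quadratic-form assembly it cross-checks.
termwise_potential <- function(state, params, contacts = list(),
                               forces = NULL, ref = NULL, tvec = NULL) {
  st <- state
  if (!is.null(tvec)) {
    st$tangents <- matrix(tvec, nrow(st$tangents), 3, byrow = TRUE)
  }
  pos <- reconstruct_positions(st)
  tall <- rbind(st$base_tangent, st$tangents)
  dt <- tall[-1L, , drop = FALSE] - tall[-nrow(tall), , drop = FALSE]
  u_e <- params$alpha * sum(rowSums(dt^2) / st$element_lengths)
  u_p <- 0
  for (ct in contacts) {
    u_p <- u_p + 0.5 * params$kappa *
      (sum(ct$normal * pos[ct$node + 1L, ]) + ct$offset)^2
  }
  w <- 0
  if (!is.null(forces)) {
    if (is.null(ref)) ref <- state$positions
    for (nm in names(forces)) {
      i <- as.integer(nm)
      w <- w + sum(forces[[nm]] * (pos[i + 1L, ] - ref[i + 1L, ]))
    }
  }
  u_e + u_p - w
}

# A random small scenario: straight catheter, 0-3 frozen plane contacts near
# the node positions, forces at the tip and one interior node.
random_scenario <- function(max_nodes = 12L, kappa = 50) {
  n <- sample(4:max_nodes, 1L)
  l <- stats::runif(1, 0.5, 2)
  init <- init_catheter(stats::rnorm(3), random_unit(), (n - 1L) * l, l)
  st <- init$state
  m <- n - 1L
  contacts <- list()
  n_con <- sample(0:3, 1L)
  used <- character(0)
  tri_id <- 0L
  while (length(contacts) < n_con) {
    node <- sample(seq_len(m), 1L)
    tri_id <- tri_id + 1L
    key <- paste(node, tri_id)
    if (key %in% used) next
    used <- c(used, key)
    nrm <- random_unit()
    sd0 <- stats::runif(1, -0.3, 0.3)
    off <- sd0 - sum(nrm * st$positions[node + 1L, ])
    contacts[[length(contacts) + 1L]] <-
      contact(node, tri_id, nrm, off, max(0, -sd0))
  }
  forces <- stats::setNames(
    list(stats::rnorm(3, sd = 0.3), stats::rnorm(3, sd = 0.3)),
    as.character(c(m, sample(seq_len(m), 1L))))
  forces <- forces[!duplicated(names(forces))]
  list(state = st, contacts = contact_set(contacts), forces = forces,
       params = material_params(1, kappa))
}

# Solve a frozen-contact scenario two ways: the package's linear system and
# a general-purpose quasi-Newton minimization of the term-wise energy.
solve_both_ways <- function(sc) {
  st <- sc$state
  Bc <- assemble_B(st)
  load <- external_load(sc$forces, st$positions)
  forms <- list(elastic_quadratic(st, sc$params),
                contact_quadratic(st, sc$contacts, sc$params, Bc$B, Bc$c),
                external_work_quadratic(st, load, Bc$B, Bc$c))
  sys <- assemble_system(forms)
  t_lin <- solve_linear(sys$A, sys$b)
  obj <- function(tv) {
    termwise_potential(st, sc$params, sc$contacts$contacts, sc$forces,
                       st$positions, tv)
  }
  o <- stats::optim(as.numeric(t(st$tangents)), obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  list(pi_linear = total_potential(forms, t_lin), pi_optim = o$value,
       t_linear = t_lin, t_optim = o$par, state = st, forms = forms,
       system = sys)
}

as_positions <- function(state, tvec) {
  st <- state
  st$tangents <- matrix(tvec, nrow(st$tangents), 3, byrow = TRUE)
  reconstruct_positions(st)
}
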