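test_that("assembled system matches the hand-derived elastic Hessian", {
  st <- catheter_state(c(0, 0, 0), c(1, 0, 0),
                       rbind(c(1, 0, 0), c(1, 0, 0)), c(1, 1), 1)
  sys <- assemble_system(list(elastic_quadratic(st, material_params(1, 0))))
  A_expected <- rbind(cbind(4 * diag(3), -2 * diag(3)),
                      cbind(-2 * diag(3), 2 * diag(3)))
  expect_equal(sys$A, A_expected)
  # zero forms give a zero system
  z <- quadratic_form(0, numeric(6))
  sys0 <- assemble_system(list(z, z))
  expect_identical(max(abs(sys0$A)), 0)
  expect_identical(max(abs(sys0$b)), 0)
  expect_error(assemble_system(list(z, quadratic_form(0, numeric(9)))),
               "mismatch")
})

test_that("A equals the finite-difference Hessian of the total potential", {
  set.seed(51)
  sc <- random_scenario(max_nodes = 6L)
  st <- sc$state
  Bc <- assemble_B(st)
  forms <- list(elastic_quadratic(st, sc$params),
                contact_quadratic(st, sc$contacts, sc$params, Bc$B, Bc$c),
                external_work_quadratic(st,
                                        external_load(sc$forces,
                                                      st$positions),
                                        Bc$B, Bc$c))
  sys <- assemble_system(forms)
  d <- length(sys$b)
  tv <- stats::rnorm(d)
  eps <- 1e-4
  H_fd <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    ei <- numeric(d); ei[i] <- eps
    ej <- numeric(d); ej[j] <- eps
    H_fd[i, j] <- H_fd[j, i] <-
      (total_potential(forms, tv + ei + ej) -
         total_potential(forms, tv + ei - ej) -
         total_potential(forms, tv - ei + ej) +
         total_potential(forms, tv - ei - ej)) / (4 * eps^2)
  }
  expect_lt(max(abs(H_fd - sys$A)) / (1 + max(abs(sys$A))), 1e-4)
})

test_that("the direct solve matches an independent factorization", {
  set.seed(52)
  expect_equal(solve_linear(diag(5), c(1, -2, 0, 4, 3)), c(1, -2, 0, 4, 3))
  M <- matrix(stats::rnorm(100), 10, 10)
  A <- crossprod(M) + diag(10)
  b <- stats::rnorm(10)
  ref <- as.numeric(qr.solve(A, b))
  expect_lt(max(abs(solve_linear(A, b) - ref)), 1e-10)
  # a singular system names the problem
  expect_error(solve_linear(matrix(0, 3, 3), numeric(3)),
               "positive-definite")
})

test_that("a free rod stays exactly straight", {
  init <- init_catheter(c(1, 2, 3), c(0, 1, 0), 12, 1.5)
  res <- solve_equilibrium(init$state, mesh = NULL)
  expect_true(res$converged)
  expect_identical(res$outer_iterations, 1L)
  expect_identical(length(res$contacts), 0L)
  m <- nrow(res$state$tangents)
  expect_lt(max(abs(res$state$tangents -
                    matrix(rep(c(0, 1, 0), each = m), m, 3))), 1e-10)
  expect_lte(res$gradient_residual, 1e-10 * (1 + sqrt(sum(res$system$b^2))))
  # nodes collinear along t0
  d <- sweep(res$state$positions, 2, c(1, 2, 3))
  expect_lt(max(abs(d[, c(1, 3)])), 1e-10)
})

test_that("the linear solve agrees with a general-purpose minimizer", {
  set.seed(53)
  for (k in 1:6) {
    sc <- random_scenario()
    both <- solve_both_ways(sc)
    expect_lt(abs(both$pi_linear - both$pi_optim) /
                (1 + abs(both$pi_optim)), 1e-6)
    pa <- as_positions(both$state, both$t_linear)
    pb <- as_positions(both$state, both$t_optim)
    expect_lt(max(abs(pa - pb)), 1e-4)
    # stationarity of the linear solution under central differences
    obj <- function(tv) total_potential(both$forms, tv)
    d <- length(both$t_linear)
    eps <- 1e-6
    g <- vapply(seq_len(d), function(i) {
      e <- numeric(d); e[i] <- eps
      (obj(both$t_linear + e) - obj(both$t_linear - e)) / (2 * eps)
    }, numeric(1))
    expect_lte(sqrt(sum(g^2)),
               1e-5 * (1 + sqrt(sum(both$system$b^2))))
  }
})

test_that("equilibrium in a curved tube resolves contact at high stiffness", {
  mesh <- curved_tube_mesh()
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 6, 2)
  tr <- simulate_sequence(init, mesh, material_params(1, 1000),
                          inputs = rep(0.5, 48), cfg = solver_config())
  n <- nrow(tr$table)
  expect_lt(tr$table$max_penetration[n], 0.1)
  final <- tr$results[[n]]
  expect_true(final$converged)
  expect_lte(final$gradient_residual,
             1e-8 * (1 + sqrt(sum(final$system$b^2))))
  expect_gt(length(final$contacts), 0L)
  # potential at the solution is not above the potential of the input state
  # for the same active set (the solve is a global quadratic minimum)
  tv <- as.numeric(t(final$state$tangents))
  sys <- final$system
  straight <- rep(c(1, 0, 0), length(tv) / 3)
  q_at <- function(t) 0.5 * sum(t * (sys$A %*% t)) - sum(sys$b * t)
  expect_lte(q_at(tv), q_at(straight) + 1e-10)
})

test_that("max penetration is non-increasing in wall stiffness", {
  mesh <- curved_tube_mesh()
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 6, 2)
  pens <- vapply(c(10, 100, 1000), function(kap) {
    tr <- simulate_sequence(init, mesh, material_params(1, kap),
                            inputs = rep(0.5, 40), cfg = solver_config())
    tr$table$max_penetration[nrow(tr$table)]
  }, numeric(1))
  expect_true(all(diff(pens) <= 1e-9))
})

test_that("aligned insertion in a straight tube never touches the wall", {
  mesh <- make_tube(tube_spec(radius = 5, length = 60,
                              circumferential_resolution = 16L,
                              axial_resolution = 30L))
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 10, 1)
  tr <- simulate_sequence(init, mesh, material_params(1, 100),
                          inputs = rep(0.1, 10), cfg = solver_config())
  expect_true(all(tr$table$converged))
  expect_identical(max(abs(tr$table$U_p)), 0)
  expect_identical(max(tr$table$max_penetration), 0)
  # equilibria all straight
  last <- tr$results[[11]]$state
  expect_lt(max(abs(last$positions[, 2:3])), 1e-9)
})

test_that("retracting after pushing restores the inserted length", {
  mesh <- make_tube(tube_spec(radius = 5, length = 60,
                              circumferential_resolution = 12L,
                              axial_resolution = 20L))
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 10, 1)
  inputs <- c(rep(0.3, 15), rep(-0.3, 15))
  tr <- simulate_sequence(init, mesh, material_params(1, 100),
                          inputs = inputs, cfg = solver_config())
  expect_lt(abs(tr$insertion$inserted_length - 10), 1e-9)
})

test_that("equilibria are equivariant under a rigid transform", {
  set.seed(55)
  mesh <- curved_tube_mesh(circ = 12L, axial = 30L)
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 6, 2)
  cfg <- solver_config()
  tr <- simulate_sequence(init, mesh, material_params(1, 500),
                          inputs = rep(0.5, 30), cfg = cfg)
  R <- random_rotation()
  s <- c(3, -7, 11)
  mesh2 <- transform_mesh(mesh, R, s)
  init2 <- init_catheter(as.numeric(R %*% c(0, 0, 0) + s),
                         as.numeric(R %*% c(1, 0, 0)), 6, 2)
  tr2 <- simulate_sequence(init2, mesh2, material_params(1, 500),
                           inputs = rep(0.5, 30), cfg = cfg)
  p1 <- tr$results[[31]]$state$positions
  p2 <- tr2$results[[31]]$state$positions
  expect_lt(max(abs(sweep(p1 %*% t(R), 2, s, "+") - p2)), 1e-8)
})

test_that("simulation traces are bit-identical across reruns", {
  mesh <- curved_tube_mesh(circ = 12L, axial = 30L)
  init <- init_catheter(c(0, 0, 0), c(1, 0, 0), 6, 2)
  run <- function() {
    simulate_sequence(init, mesh, material_params(1, 300),
                      inputs = rep(0.5, 20), cfg = solver_config())$table
  }
  expect_identical(run(), run())
})

test_that("tangent-space solve equals the paper's composed position solve", {
  # A B^{-1} x = b solved for x, then t = B^{-1} (x - c), on a small case
  set.seed(56)
  sc <- random_scenario(max_nodes = 6L)
  both <- solve_both_ways(sc)
  Bc <- assemble_B(sc$state)
  sys <- both$system
  ABinv <- sys$A %*% solve(Bc$B)
  x <- qr.solve(ABinv, sys$b + ABinv %*% Bc$c)
  t_from_x <- solve(Bc$B, x - Bc$c)
  expect_lt(max(abs(as.numeric(t_from_x) - both$t_linear)), 1e-8)
})
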