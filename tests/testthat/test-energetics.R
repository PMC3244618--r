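test_that("bending energy matches term-by-term summation", {
  # hand example: alpha=1, h=1, t0=(1,0,0), t1=(0,1,0), t2=(1,0,0)
  st <- catheter_state(c(0, 0, 0), c(1, 0, 0),
                       rbind(c(0, 1, 0), c(1, 0, 0)), c(1, 1), 1)
  f <- elastic_quadratic(st, material_params(1, 0))
  expect_equal(eval_form(f, as.numeric(t(st$tangents))), 4)
  # zero at the straight configuration
  straight <- init_catheter(c(0, 0, 0), c(0, 1, 0), 4, 1)$state
  fs <- elastic_quadratic(straight, material_params(3, 0))
  expect_equal(eval_form(fs, as.numeric(t(straight$tangents))), 0,
               tolerance = 1e-14)
  # random states against the independent term-wise oracle
  set.seed(31)
  for (k in 1:8) {
    m <- sample(3:8, 1L)
    h <- c(stats::runif(1, 0.2, 1.1), rep(1.1, m - 1L))
    st <- catheter_state(stats::rnorm(3), random_unit(),
                         matrix(stats::rnorm(3 * m), m, 3), h, 1.1)
    params <- material_params(stats::runif(1, 0.5, 3), 0)
    f <- elastic_quadratic(st, params)
    tv <- as.numeric(t(st$tangents))
    expect_equal(eval_form(f, tv), termwise_potential(st, params),
                 tolerance = 1e-10)
  }
})

test_that("contact penalty implements Hooke's law on the plane distance", {
  st <- init_catheter(c(0, 0, 0), c(1, 0, 0), 4, 1)$state
  Bc <- assemble_B(st)
  params <- material_params(1, 80)
  # empty set -> zero form
  f0 <- contact_quadratic(st, contact_set(), params, Bc$B, Bc$c)
  expect_identical(max(abs(f0$H)), 0)
  expect_identical(max(abs(f0$g)), 0)
  expect_identical(f0$c, 0)
  # single contact: energy = kappa/2 * (signed distance)^2
  nrm <- c(0, -1, 0)
  p_depth <- 0.37
  off <- -sum(nrm * st$positions[4, ]) - p_depth    # node at distance -p
  ct <- contact(3L, 1L, nrm, off, p_depth)
  f1 <- contact_quadratic(st, contact_set(list(ct)), params, Bc$B, Bc$c)
  tv <- as.numeric(t(st$tangents))
  expect_equal(eval_form(f1, tv), 0.5 * 80 * p_depth^2, tolerance = 1e-10)
  # two contacts on one node add
  nrm2 <- random_unit()
  off2 <- -sum(nrm2 * st$positions[4, ]) + 0.2
  ct2 <- contact(3L, 2L, nrm2, off2, 0)
  f2 <- contact_quadratic(st, contact_set(list(ct2)), params, Bc$B, Bc$c)
  f12 <- contact_quadratic(st, contact_set(list(ct, ct2)), params, Bc$B, Bc$c)
  expect_equal(eval_form(f12, tv), eval_form(f1, tv) + eval_form(f2, tv),
               tolerance = 1e-10)
  # base-node contact is rejected as a boundary contact
  expect_error(contact(0L, 1L, nrm, 0, 0), "base")
})

test_that("external work is linear with the standard sign convention", {
  st <- init_catheter(c(0, 0, 0), c(1, 0, 0), 4, 1)$state
  Bc <- assemble_B(st)
  tv <- as.numeric(t(st$tangents))
  # zero force and zero displacement both give zero
  fz <- external_work_quadratic(st, external_load(), Bc$B, Bc$c)
  expect_identical(max(abs(fz$H)), 0)
  expect_equal(eval_form(fz, tv), 0)
  load0 <- external_load(list(`3` = c(0, 0, 1)), st$positions)
  f0 <- external_work_quadratic(st, load0, Bc$B, Bc$c)
  expect_equal(eval_form(f0, tv), 0, tolerance = 1e-12)
  # tip force with a known displacement contributes -f.d to the objective
  m <- nrow(st$tangents)
  load <- external_load(stats::setNames(list(c(0, 0, 1)), m), st$positions)
  f <- external_work_quadratic(st, load, Bc$B, Bc$c)
  moved <- tv
  # displace the tip by (0,0,2): add 4/h to the z of the last tangent
  moved[3 * m] <- moved[3 * m] + 2 * 2 / st$element_lengths[m]
  disp <- as_positions(st, moved)[m + 1L, ] - st$positions[m + 1L, ]
  expect_equal(disp, c(0, 0, 2), tolerance = 1e-12)
  expect_equal(eval_form(f, moved), -2, tolerance = 1e-10)
  # paper-literal convention flips the sign
  fp <- external_work_quadratic(st, load, Bc$B, Bc$c,
                                sign_convention = "paper_literal")
  expect_equal(eval_form(fp, moved), 2, tolerance = 1e-10)
})

test_that("total potential is additive and has the quadratic-form gradient", {
  set.seed(33)
  sc <- random_scenario()
  st <- sc$state
  Bc <- assemble_B(st)
  forms <- list(
    elastic_quadratic(st, sc$params),
    contact_quadratic(st, sc$contacts, sc$params, Bc$B, Bc$c),
    external_work_quadratic(st, external_load(sc$forces, st$positions),
                            Bc$B, Bc$c))
  m <- nrow(st$tangents)
  tv <- stats::rnorm(3 * m)
  total <- total_potential(forms, tv)
  expect_equal(total, sum(vapply(forms, eval_form, numeric(1), t = tv)),
               tolerance = 1e-12)
  # central-difference gradient equals H t + g of the summed form
  sys <- assemble_system(forms)
  grad <- as.numeric(sys$A %*% tv) - sys$b
  eps <- 1e-6
  fd <- vapply(seq_len(3 * m), function(i) {
    e <- numeric(3 * m); e[i] <- eps
    (total_potential(forms, tv + e) - total_potential(forms, tv - e)) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(fd - grad)) / (1 + max(abs(grad))), 1e-5)
})

test_that("every energy form is convex and exactly quadratic", {
  set.seed(34)
  for (k in 1:5) {
    sc <- random_scenario()
    st <- sc$state
    Bc <- assemble_B(st)
    forms <- list(
      elastic_quadratic(st, sc$params),
      contact_quadratic(st, sc$contacts, sc$params, Bc$B, Bc$c),
      external_work_quadratic(st, external_load(sc$forces, st$positions),
                              Bc$B, Bc$c))
    m <- nrow(st$tangents)
    for (f in forms) {
      expect_identical(max(abs(f$H - t(f$H))), 0)
      ev <- eigen(f$H, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
      # E(t) equals its own second-order Taylor expansion exactly
      tv <- stats::rnorm(3 * m)
      taylor <- f$c + sum(f$g * tv) + 0.5 * sum(tv * (f$H %*% tv))
      expect_equal(eval_form(f, tv), taylor, tolerance = 1e-12)
    }
    # the elastic form restricted to the unknowns is positive-definite
    ev_el <- eigen(forms[[1]]$H, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev_el), 0)
  }
})

test_that("bending energy is invariant to a shared tangent offset", {
  set.seed(35)
  m <- 6L
  tg <- matrix(stats::rnorm(3 * m), m, 3)
  h <- rep(0.8, m)
  st <- catheter_state(c(0, 0, 0), c(1, 0, 0), tg, h, 0.8)
  params <- material_params(1.7, 0)
  u0 <- termwise_potential(st, params)
  shift <- stats::rnorm(3)
  st2 <- st
  st2$base_tangent <- st$base_tangent + shift   # bypasses unit check on purpose
  st2$tangents <- sweep(st$tangents, 2, shift, "+")
  expect_equal(termwise_potential(st2, params), u0, tolerance = 1e-10)
})

test_that("all energy terms are invariant under a common rotation", {
  set.seed(36)
  sc <- random_scenario()
  st <- sc$state
  Bc <- assemble_B(st)
  load <- external_load(sc$forces, st$positions)
  forms <- list(elastic_quadratic(st, sc$params),
                contact_quadratic(st, sc$contacts, sc$params, Bc$B, Bc$c),
                external_work_quadratic(st, load, Bc$B, Bc$c))
  tv <- stats::rnorm(3 * nrow(st$tangents), sd = 0.5) +
    as.numeric(t(st$tangents))
  R <- random_rotation()
  rot_state <- catheter_state(as.numeric(R %*% st$base_position),
                              as.numeric(R %*% st$base_tangent),
                              st$tangents %*% t(R), st$element_lengths,
                              st$segment_length)
  # rotating the scene about the origin maps the plane {n.x + d = 0} to
  # {(Rn).x + d = 0}
  rot_contacts <- contact_set(lapply(sc$contacts$contacts, function(ct) {
    contact(ct$node, ct$triangle, as.numeric(R %*% ct$normal), ct$offset,
            ct$penetration)
  }))
  rot_forces <- lapply(sc$forces, function(f) as.numeric(R %*% f))
  Bc2 <- assemble_B(rot_state)
  rot_load <- external_load(rot_forces, st$positions %*% t(R))
  forms2 <- list(elastic_quadratic(rot_state, sc$params),
                 contact_quadratic(rot_state, rot_contacts, sc$params,
                                   Bc2$B, Bc2$c),
                 external_work_quadratic(rot_state, rot_load, Bc2$B, Bc2$c))
  tv2 <- as.numeric(t(matrix(tv, ncol = 3, byrow = TRUE) %*% t(R)))
  expect_equal(eval_form(forms2[[1]], tv2), eval_form(forms[[1]], tv),
               tolerance = 1e-9)
  expect_equal(eval_form(forms2[[3]], tv2), eval_form(forms[[3]], tv),
               tolerance = 1e-9)
  # the contact plane n.x + d rotates to (Rn).(Rx) + d: same distances
  expect_equal(eval_form(forms2[[2]], tv2), eval_form(forms[[2]], tv),
               tolerance = 1e-9)
})
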