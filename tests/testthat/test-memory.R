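test_that("scalar-case ingredients match hand-derived closed forms", {
  for (x1 in c(0.4, 1.5, 3.2)) {
    ing <- memory_ingredients(bistable2, bistable2_part, x1)
    x2 <- bi_xb_star(x1)
    expect_equal(ing$f0[1, 1], bi_dR1_dx2(x1, x2), tolerance = 1e-10)
    expect_equal(ing$J[1, 1], -1)
    expect_equal(ing$Lambda[1, 1], bi_lambda(x1), tolerance = 1e-10)
    expect_equal(ing$l[1, 1], bi_lambda(x1), tolerance = 1e-10)
    expect_equal(as.numeric(ing$c), bi_c(x1), tolerance = 1e-10)
    # cross-check derivatives against finite differences
    Jfd <- jacobian_full(bistable2, ing$x, mode = "fd")
    expect_equal(ing$B[1, 1], Jfd[1, 2], tolerance = 1e-5)
  }
})

test_that("the memory prefactor c vanishes at the saddle", {
  fp <- find_fixed_points(bistable2, c(0, 10), system = "full")
  saddle <- fp$x1[fp$stability == "saddle"]
  ing <- memory_ingredients(bistable2, bistable2_part, saddle)
  expect_lt(abs(ing$c), 1e-12)
})

test_that("empty bulk yields empty ingredients and zero memory", {
  p_all <- subnetwork_partition(bistable2, c("x1", "x2"))
  ing <- memory_ingredients(bistable2, p_all, c(1, 2))
  expect_equal(dim(ing$J), c(0L, 0L))
  expect_length(ing$c, 0L)
  mf <- memory_function(bistable2, p_all, c(1, 2), tau = c(0, 1, 5))
  expect_true(all(mf$x1 == 0 & mf$x2 == 0))
})

test_that("propagator starts at the identity and solves the flow-ODE", {
  expect_equal(propagator(linbulk, linbulk_part, 1.3, 0), diag(2))
  # scalar-bulk case: G(tau) = exp(int_0^tau Lambda(phi(tau')) dtau'),
  # checked against adaptive quadrature of the closed-form generator
  x1 <- 1.5; tau <- 2
  G <- propagator(bistable2, bistable2_part, x1, tau)
  fl <- qss_flow(bistable2, bistable2_part, x1, seq(0, tau, length.out = 401),
                 rtol = 1e-12, atol = 1e-14)
  lam_t <- function(t) bi_lambda(interpolate_trajectory(fl, t)[, 1])
  I <- stats::integrate(function(t) vapply(t, lam_t, numeric(1)),
                        0, tau, rel.tol = 1e-12)$value
  expect_equal(G[1, 1], exp(I), tolerance = 1e-8)
})

test_that("at a drift fixed point the propagator is the matrix exponential", {
  fp <- find_fixed_points(linbulk, c(0, 5), partition = linbulk_part,
                          system = "qss")
  xstar <- fp[[linbulk_part$sub_names]][fp$stability == "stable"][1]
  ing <- memory_ingredients(linbulk, linbulk_part, xstar)
  for (tau in c(0.5, 2, 5)) {
    G <- propagator(linbulk, linbulk_part, xstar, tau)
    E <- as.matrix(Matrix::expm(tau * ing$Lambda))
    expect_lt(max(abs(G - E)), 1e-8)
  }
})

test_that("memory is computed from scratch by the scalar-bulk oracle", {
  # independent route for the two-node switch: hand-derived drift, generator
  # and couplings + generic ODE quadrature; no package memory code involved
  x1 <- 1.2
  taus <- seq(0, 4, length.out = 9)
  flow_oracle <- deSolve::ode(
    y = c(x = x1, I = 0), times = taus,
    func = function(t, y, p) list(c(bi_drift(y[1]), bi_lambda(y[1]))),
    parms = NULL, rtol = 1e-12, atol = 1e-14
  )
  M_oracle <- vapply(seq_along(taus), function(k) {
    phi <- flow_oracle[k, 2]
    G <- exp(flow_oracle[k, 3])
    bi_dR1_dx2(phi, bi_xb_star(phi)) * G * bi_c(x1)
  }, numeric(1))
  mf <- memory_function(bistable2, bistable2_part, x1, taus)
  expect_equal(mf$x1, M_oracle, tolerance = 1e-8)
})

test_that("memory vanishes at every reduced fixed point", {
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  taus <- seq(0, 50, length.out = 26)
  for (x1 in fp$x1) {
    mf <- memory_function(bistable2, bistable2_part, x1, taus)
    expect_lt(max_abs(mf$x1), 1e-10)
  }
})

test_that("memory amplitude opposes the drift between fixed points", {
  # between the saddle (1.46) and the high state (6.0) the drift is positive
  for (x1 in c(1.6, 2.5, 4)) {
    v <- as.numeric(qss_drift(bistable2, bistable2_part, x1))
    amp <- as.numeric(memory_amplitude(bistable2, bistable2_part, x1))
    expect_true(sign(amp) == -sign(v))
  }
  # and below the low state, drift negative, memory positive
  v <- as.numeric(qss_drift(bistable2, bistable2_part, 1.0))
  amp <- as.numeric(memory_amplitude(bistable2, bistable2_part, 1.0))
  expect_true(sign(amp) == -sign(v))
})

test_that("linearized kernel reproduces the full linearized system exactly", {
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  xhigh <- max(fp$x1)
  K <- linearized_kernel(bistable2, bistable2_part, xhigh)
  # scalar case: K(tau) is a scalar multiple of exp(Lambda* tau)
  k0 <- kernel_matrix(K, 0)[1, 1]
  lam <- K$Lambda[1, 1]
  for (tau in c(0.5, 1.5, 3)) {
    expect_equal(kernel_matrix(K, tau)[1, 1], k0 * exp(lam * tau),
                 tolerance = 1e-10)
  }
  # impulse response vs direct integration of the full linearized ODE
  ing <- memory_ingredients(bistable2, bistable2_part, xhigh)
  Jf <- jacobian_full(bistable2, ing$x)
  times <- seq(0, 20, length.out = 201)
  xi0 <- 0.1
  ir <- impulse_response(K, xi0, times)
  z0 <- c(xi0, drop(-solve(ing$J, ing$A) * xi0))
  ref <- deSolve::ode(z0, times, function(t, y, p) list(drop(Jf %*% y)),
                      NULL, rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(ir$x1 - ref[, 2])), 1e-6)
  # not-a-fixed-point precondition
  expect_error(linearized_kernel(bistable2, bistable2_part, 2.0),
               "not a fixed point")
})

test_that("kernel is zero when the bulk does not feed back", {
  m <- network_model(c("x1", "y"),
                     c(x1 = "2/(1 + x1^2) - x1", y = "x1 - 2*y"))
  p <- subnetwork_partition(m, "x1")
  fp <- find_fixed_points(m, c(0, 3), partition = p, system = "qss")
  K <- linearized_kernel(m, p, fp$x1[1])
  expect_equal(kernel_matrix(K, 0.7), matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("random force is linear in the bulk deviation and zero at QSS", {
  xs <- 1.5
  xbstar <- as.numeric(solve_qss(bistable2, bistable2_part, xs))
  taus <- c(0, 0.5, 2)
  f0 <- random_force(bistable2, bistable2_part, xs, xbstar, taus)
  expect_true(all(f0$x1 == 0))
  f1 <- random_force(bistable2, bistable2_part, xs, xbstar + 0.2, taus)
  f2 <- random_force(bistable2, bistable2_part, xs, xbstar + 0.4, taus)
  expect_equal(f2$x1, 2 * f1$x1, tolerance = 1e-12)
  # tau = 0: the linearization of R^s in the bulk deviation
  ing <- memory_ingredients(bistable2, bistable2_part, xs)
  expect_equal(f1$x1[1], ing$B[1, 1] * 0.2, tolerance = 1e-10)
  # ... which matches the exact rate difference for small deviations
  eps <- 1e-6
  fe <- random_force(bistable2, bistable2_part, xs, xbstar + eps, 0)
  exact <- evaluate_rates(bistable2, c(xs, xbstar + eps))[1] -
    evaluate_rates(bistable2, c(xs, xbstar))[1]
  expect_equal(fe$x1[1], unname(exact), tolerance = 1e-5)
})
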