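test_that("full integrator matches the matrix-exponential solution of a linear ODE", {
  A <- matrix(c(-1, 0.4, 0.3, -1.5), 2, 2, byrow = TRUE)
  m <- network_model(c("x1", "x2"),
                     c(x1 = "-1*x1 + 0.4*x2", x2 = "0.3*x1 - 1.5*x2"))
  x0 <- c(2, -1)
  times <- seq(0, 5, length.out = 26)
  tr <- integrate_full(m, x0, times, rtol = 1e-11, atol = 1e-13)
  for (k in c(5, 13, 26)) {
    ref <- drop(as.matrix(Matrix::expm(times[k] * A)) %*% x0)
    expect_equal(as.numeric(tr[k, c("x1", "x2")]), ref, tolerance = 1e-8)
  }
})

test_that("bistable transient reaches the printed high state with bulk at QSS", {
  # start slightly above the saddle, bulk initialized at QSS
  tr <- integrate_full(bistable2, 1.5, seq(0, 50, length.out = 201),
                       partition = bistable2_part)
  final <- as.numeric(tr[201, c("x1", "x2")])
  expect_lt(max(abs(final - c(6.000, 0.028))), 1e-3)
})

test_that("dense trajectory output is exact at nodes and accurate between", {
  times <- seq(0, 10, length.out = 51)
  tr <- integrate_full(bistable2, c(1.5, 2), times, rtol = 1e-10, atol = 1e-12)
  expect_equal(interpolate_trajectory(tr, times),
               as.matrix(tr[, c("x1", "x2")]), ignore_attr = TRUE)
  fine <- integrate_full(bistable2, c(1.5, 2), seq(0, 10, length.out = 401),
                         rtol = 1e-10, atol = 1e-12)
  probe <- seq(0.11, 9.9, length.out = 37)
  # O(h^4) Hermite error on the coarse 51-node grid (h = 0.2)
  expect_lt(max(abs(interpolate_trajectory(tr, probe) -
                    interpolate_trajectory(fine, probe))), 1e-4)
  # and the 401-node grid is accurate to far below integrator tolerance
  finer <- integrate_full(bistable2, c(1.5, 2), seq(0, 10, length.out = 1601),
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(interpolate_trajectory(fine, probe) -
                    interpolate_trajectory(finer, probe))), 1e-7)
})

test_that("QSS reduction reaches steady state faster than the full system", {
  times <- seq(0, 50, length.out = 501)
  full <- integrate_full(bistable2, 1.5, times, partition = bistable2_part)
  qss <- integrate_qss(bistable2, bistable2_part, 1.5, times)
  target <- full$x1[501]
  t_settle <- function(x, t) t[min(which(abs(x - target) < 0.01 * target))]
  expect_lt(t_settle(qss$x1, times), t_settle(full$x1, times))
})

test_that("empty-bulk partitions short-circuit to the full dynamics", {
  p_all <- subnetwork_partition(bistable2, c("x1", "x2"))
  times <- seq(0, 5, length.out = 21)
  full <- integrate_full(bistable2, c(1.2, 0.8), times)
  for (f in list(integrate_qss, integrate_zms)) {
    tr <- f(bistable2, p_all, c(1.2, 0.8), times)
    expect_lt(max(abs(tr$x1 - full$x1)), 1e-12)
    expect_lt(max(abs(tr$x2 - full$x2)), 1e-12)
  }
})

test_that("sustained repressilator oscillations do not decay", {
  tr <- integrate_full(repressilator, c(1.8, 1.1), 150,
                       partition = repressilator_part)
  cls <- classify_oscillation(tr, observable = "x1")
  expect_identical(cls$verdict, "sustained-oscillatory")
  expect_true(abs(cls$decay_ratio - 1) < 0.01)
})

test_that("ZMn tracks the full transient better than QSS", {
  times <- seq(0, 30, length.out = 301)
  full <- integrate_full(bistable2, 1.4, times, partition = bistable2_part,
                         rtol = 1e-10, atol = 1e-12)
  zmn <- integrate_zmn(bistable2, bistable2_part, 1.4, 30, h = 30 / 400)
  qss <- integrate_qss(bistable2, bistable2_part, 1.4, times)
  gap <- 6.0 - 0.028
  ref_at <- interpolate_trajectory(full, zmn$time)[, 1]
  err_zmn <- max(abs(zmn$x1 - ref_at)) / gap
  err_qss <- max(abs(qss$x1 - interpolate_trajectory(full, times)[, 1])) / gap
  expect_lt(err_zmn, 0.05)
  expect_gt(err_qss, err_zmn)
})

test_that("ZMn equals QSS when the bulk does not feed back", {
  m <- network_model(c("x1", "y"),
                     c(x1 = "2/(1 + x1^2) - x1", y = "x1 - 2*y"))
  p <- subnetwork_partition(m, "x1")
  z <- integrate_zmn(m, p, 0.3, 10, h = 10 / 800)
  q <- integrate_qss(m, p, 0.3, z$time, rtol = 1e-11, atol = 1e-13)
  # identical dynamics; difference is only the outer stepper's O(h^2) error
  expect_lt(max(abs(z$x1 - q$x1)), 5e-5)
  # and the memory function itself is identically zero
  mf <- memory_function(m, p, 0.7, c(0, 1, 3))
  expect_true(all(mf$x1 == 0))
})

test_that("halving the ZMn history step converges at second order", {
  z1 <- integrate_zmn(bistable2, bistable2_part, 1.4, 10, h = 10 / 100)
  z2 <- integrate_zmn(bistable2, bistable2_part, 1.4, 10, h = 10 / 200)
  z3 <- integrate_zmn(bistable2, bistable2_part, 1.4, 10, h = 10 / 400)
  e1 <- max(abs(interpolate_trajectory(z1, z3$time)[, 1] - z3$x1))
  e2 <- max(abs(interpolate_trajectory(z2, z3$time)[, 1] - z3$x1))
  expect_gt(e1 / e2, 3)   # ~4 for a second-order method
  expect_lt(e1 / e2, 6)
})

test_that("ZMs auxiliary ODE reproduces the nested-quadrature memory integral", {
  times <- seq(0, 5, length.out = 2001)
  zs <- integrate_zms(bistable2, bistable2_part, 1.4, times,
                      rtol = 1e-11, atol = 1e-13)
  m_ode <- attr(zs, "aux")[, 1]
  # oracle: m(t) = int_0^t exp(Phi(t) - Phi(t')) c(t') dt' with Phi the
  # time-ordered integral of the generator along the actual trajectory
  lam <- vapply(zs$x1, bi_lambda, numeric(1))
  cv <- vapply(zs$x1, bi_c, numeric(1))
  Phi <- deSolve::ode(
    y = 0, times = times,
    func = function(t, y, p) {
      list(bi_lambda(interpolate_trajectory(zs, t)[, 1]))
    }, parms = NULL, rtol = 1e-12, atol = 1e-14
  )[, 2]
  idx <- seq(1, 2001, by = 100)    # check every 0.25 time units
  m_quad <- vapply(idx, function(k) {
    if (k == 1) return(0)
    integrand <- exp(Phi[k] - Phi[1:k]) * cv[1:k]
    simpson(times[1:k], integrand)
  }, numeric(1))
  expect_lt(max(abs(m_ode[idx] - m_quad)), 1e-6)
  # the memory terms (B m) agree equally well
  Bv <- vapply(zs$x1, function(x) bi_dR1_dx2(x, bi_xb_star(x)), numeric(1))
  expect_lt(max(abs(Bv[idx] * (m_ode[idx] - m_quad))), 1e-6)
})

test_that("ZMs is exact for rates linear in the bulk", {
  times <- seq(0, 50, length.out = 501)
  full <- integrate_full(linbulk, 2, times, partition = linbulk_part,
                         rtol = 1e-11, atol = 1e-13)
  zms <- integrate_zms(linbulk, linbulk_part, 2, times,
                       rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(full$x1 - zms$x1)), 1e-6)
})

test_that("ZMs rests at stable fixed points with relaxed memory", {
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  xstar <- max(fp$x1)
  times <- seq(0, 20, length.out = 101)
  tr <- integrate_zms(bistable2, bistable2_part, xstar, times)
  expect_lt(max(abs(tr$x1 - xstar)), 1e-7)
  m <- attr(tr, "aux")[, 1]
  expect_lt(max(abs(m)), 1e-9)     # c = 0 at the fixed point, so m stays 0
})

test_that("ZMn and ZMs agree for small perturbations around a fixed point", {
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  xstar <- max(fp$x1)
  dev0 <- 1e-3 * xstar
  zn <- integrate_zmn(bistable2, bistable2_part, xstar + dev0, 10, h = 10 / 1000)
  zs <- integrate_zms(bistable2, bistable2_part, xstar + dev0, zn$time,
                      rtol = 1e-12, atol = 1e-15)
  expect_lt(max(abs(zn$x1 - zs$x1)) / dev0, 1e-5)
})

test_that("ZMs relaxation rate matches the slowest full-system eigenvalue", {
  # asymmetric stable state of the three-node network: well-separated
  # eigenvalues (about -0.17 vs -0.98)
  fp <- find_fixed_points(tetrastable, c(0, 6), system = "full",
                          n_starts = 128L)
  st <- stable_points(fp)
  row <- which(st[, 1] < 1 & st[, 2] > 2)[1]
  xstar_full <- st[row, ]
  ev <- eigen(jacobian_full(tetrastable, xstar_full), only.values = TRUE)$values
  slowest <- max(Re(ev))
  xs_star <- xstar_full[tetrastable_part$sub]
  times <- seq(0, 20, length.out = 401)
  tr <- integrate_zms(tetrastable, tetrastable_part,
                      xs_star + c(1e-3, 1e-3), times,
                      rtol = 1e-12, atol = 1e-15)
  dev <- abs(tr$x1 - xs_star[1])
  sel <- times >= 8 & times <= 18
  rate <- unname(coef(lm(log(dev[sel]) ~ times[sel]))[2])
  expect_lt(abs(rate - slowest) / abs(slowest), 0.01)
})
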