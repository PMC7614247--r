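test_that("bulk QSS matches closed forms", {
  # two-node switch: x2* = a/(1 + x1^n)
  for (x1 in c(0.2, 1.46, 3, 6)) {
    expect_equal(as.numeric(solve_qss(bistable2, bistable2_part, x1)),
                 bi_xb_star(x1), tolerance = 1e-12)
  }
  # repressilator, bulk {x3}: x3* = a/(1 + x2^n)
  xs <- c(1.1, 0.4)
  expect_equal(as.numeric(solve_qss(repressilator, repressilator_part, xs)),
               5 / (1 + 0.4^3), tolerance = 1e-12)
  # linear bulk: x^b* = -D^{-1} g(x^s), via a linear-solve oracle
  xs1 <- 1.7
  x0 <- c(xs1, 0, 0)
  g <- evaluate_rates(linbulk, x0)[2:3]
  D <- jacobian_full(linbulk, x0)[2:3, 2:3]
  expect_equal(as.numeric(solve_qss(linbulk, linbulk_part, xs1)),
               as.numeric(-solve(D, g)), tolerance = 1e-10)
})

test_that("multiple bulk roots trigger a uniqueness-violation error", {
  m <- network_model(
    c("x1", "y"),
    c(x1 = "-x1", y = "y - y^3 + 0.01*x1")
  )
  p <- subnetwork_partition(m, "x1")
  expect_error(solve_qss(m, p, 0.5), "not unique")
})

test_that("QSS drift composes closed forms and vanishes at full fixed points", {
  for (x1 in c(0.5, 1.2, 2.5, 5)) {
    expect_equal(as.numeric(qss_drift(bistable2, bistable2_part, x1)),
                 bi_drift(x1), tolerance = 1e-12)
  }
  fp <- find_fixed_points(bistable2, c(0, 10), system = "full")
  for (i in seq_len(nrow(fp))) {
    expect_lt(max_abs(qss_drift(bistable2, bistable2_part, fp$x1[i])), 1e-8)
  }
  # empty bulk: drift is just the rate vector
  p_all <- subnetwork_partition(bistable2, c("x1", "x2"))
  xs <- c(1.3, 0.6)
  expect_equal(qss_drift(bistable2, p_all, xs), evaluate_rates(bistable2, xs))
})

test_that("QSS flow respects fixed points, monotonicity and the semigroup law", {
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  xstay <- fp$x1[fp$stability == "stable"][1]
  tr <- qss_flow(bistable2, bistable2_part, xstay, seq(0, 10, length.out = 51))
  expect_lt(max(abs(tr$x1 - xstay)), 1e-8)

  # from x1 = 1.5 (above the saddle) the drift is positive: monotone rise to
  # the high state
  tr2 <- qss_flow(bistable2, bistable2_part, 1.5, seq(0, 30, length.out = 301))
  expect_true(all(diff(tr2$x1) > -1e-10))
  expect_equal(tr2$x1[301], max(fp$x1), tolerance = 1e-4)

  # semigroup property phi(phi(x, t1), t2) = phi(x, t1 + t2)
  t1 <- 2.3; t2 <- 4.1
  a1 <- qss_flow(bistable2, bistable2_part, 1.5, c(0, t1),
                 rtol = 1e-11, atol = 1e-13)
  mid <- a1$x1[2]
  a2 <- qss_flow(bistable2, bistable2_part, mid, c(0, t2),
                 rtol = 1e-11, atol = 1e-13)
  a12 <- qss_flow(bistable2, bistable2_part, 1.5, c(0, t1 + t2),
                  rtol = 1e-11, atol = 1e-13)
  expect_equal(a2$x1[2], a12$x1[2], tolerance = 1e-8)
})

test_that("warm-started QSS continuation is jump-free along a path", {
  path <- seq(0.05, 6, length.out = 200)
  cache <- new.env()
  xb <- vapply(path, function(x1) {
    as.numeric(solve_qss(bistable2, bistable2_part, x1, cache = cache))
  }, numeric(1))
  steps <- abs(diff(xb))
  # no jump exceeding 10x the local step-size scale of the closed form
  ref <- abs(diff(bi_xb_star(path)))
  expect_true(all(steps <= 10 * pmax(ref, 1e-8)))
  expect_equal(xb, bi_xb_star(path), tolerance = 1e-10)
})

test_that("two-node switch fixed points match the printed values", {
  fp <- find_fixed_points(bistable2, c(0, 10), system = "full")
  expect_equal(nrow(fp), 3L)
  expect_equal(sum(fp$stability == "stable"), 2L)
  expect_equal(sum(fp$stability == "saddle"), 1L)
  saddle <- fp[fp$stability == "saddle", ]
  expect_equal(round(c(saddle$x1, saddle$x2), 3), c(1.460, 1.460))
  hi <- fp[fp$stability == "stable" & fp$x1 > 1, ]
  expect_equal(round(c(hi$x1, hi$x2), 3), c(6.000, 0.028))
})

test_that("three-node cross-repression network is tetrastable", {
  fp <- find_fixed_points(tetrastable, c(0, 6), system = "full",
                          n_starts = 128L)
  st <- stable_points(fp)
  expect_equal(nrow(st), 4L)
  # symmetric point: all coordinates equal the root of 2x^3 + x = 4
  xsym <- uniroot(function(x) 2 * x^3 + x - 4, c(0, 2), tol = 1e-14)$root
  sym_row <- which(apply(st, 1, function(r) diff(range(r)) < 1e-8))
  expect_length(sym_row, 1L)
  expect_equal(unname(st[sym_row, ]), rep(xsym, 3), tolerance = 1e-8)
  # the other three are permutations of one (high, low, low) pattern
  rest <- st[-sym_row, , drop = FALSE]
  expect_true(all(apply(rest, 1, function(r) sum(r > 2) == 1)))
})

test_that("a linear contraction has a single stable fixed point at the origin", {
  m <- network_model(c("x1", "x2"), c(x1 = "-x1", x2 = "-2*x2"))
  fp <- find_fixed_points(m, c(-3, 3), system = "full")
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$stability, "stable")
  expect_equal(c(fp$x1, fp$x2), c(0, 0), tolerance = 1e-10)
})

test_that("full fixed points project onto QSS-drift fixed points", {
  cases <- list(
    list(m = bistable2, p = bistable2_part, box = c(0, 10)),
    list(m = tetrastable, p = tetrastable_part, box = c(0, 6)),
    list(m = linbulk, p = linbulk_part, box = c(0, 5))
  )
  for (cs in cases) {
    fp <- find_fixed_points(cs$m, cs$box, system = "full", n_starts = 128L)
    for (i in seq_len(nrow(fp))) {
      xs <- as.numeric(fp[i, cs$p$sub_names])
      expect_lt(max_abs(qss_drift(cs$m, cs$p, xs)), 1e-8)
    }
  }
})

test_that("ZMs steady states coincide with QSS-drift fixed points", {
  fq <- find_fixed_points(tetrastable, c(0, 6), partition = tetrastable_part,
                          system = "qss", n_starts = 128L)
  fz <- find_fixed_points(tetrastable, c(0, 6), partition = tetrastable_part,
                          system = "zms", n_starts = 128L)
  expect_equal(nrow(fq), nrow(fz))
  cq <- as.matrix(fq[, tetrastable_part$sub_names])
  cz <- as.matrix(fz[, tetrastable_part$sub_names])
  expect_lt(max(abs(cq - cz)), 1e-8)
  # reduced stability agrees with the full system's (similar Jacobians)
  expect_identical(fq$stability, fz$stability)
})
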