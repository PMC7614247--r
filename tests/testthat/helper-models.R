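# shared fixtures and small oracles used across test files

bistable2 <- fixture_model("bistable2")
bistable2_part <- default_partition(bistable2)

tetrastable <- fixture_model("multistable_or", N = 3)
tetrastable_part <- default_partition(tetrastable)

repressilator <- fixture_model("repressilator")
repressilator_part <- default_partition(repressilator)

linbulk <- fixture_model("linear_bulk_demo")
linbulk_part <- default_partition(linbulk)

neural4 <- fixture_model("neural_tube4")
neural4_part <- default_partition(neural4)

# closed-form pieces of the two-node switch (a = 6, n = 3), derived by hand
# from dx1/dt = a/(1+x2^n) - x1, dx2/dt = a/(1+x1^n) - x2
bi_a <- 6; bi_n <- 3
bi_xb_star <- function(x1) bi_a / (1 + x1^bi_n)                 # bulk QSS
bi_drift <- function(x1) bi_a / (1 + bi_xb_star(x1)^bi_n) - x1  # QSS drift
bi_dR1_dx2 <- function(x1, x2) -bi_a * bi_n * x2^(bi_n - 1) / (1 + x2^bi_n)^2
bi_dR2_dx1 <- function(x1, x2) -bi_a * bi_n * x1^(bi_n - 1) / (1 + x1^bi_n)^2
bi_lambda <- function(x1) {
  x2 <- bi_xb_star(x1)
  -1 - bi_dR2_dx1(x1, x2) * bi_dR1_dx2(x1, x2)
}
bi_c <- function(x1) {
  x2 <- bi_xb_star(x1)
  -bi_dR2_dx1(x1, x2) * (bi_a / (1 + x2^bi_n) - x1)
}

# composite Simpson rule on a uniform grid (odd number of points)
simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n %% 2 == 1)
  h <- x[2] - x[1]
  h / 3 * sum(y * c(1, rep(c(4, 2), (n - 3) / 2), 4, 1))
}

max_abs <- function(x) max(abs(x))

# deterministic pseudo-random positive states
sample_states <- function(n_states, dim, lo = 0.1, hi = 3, seed = 42) {
  withr::with_seed(seed, matrix(stats::runif(n_states * dim, lo, hi),
                                n_states, dim))
}
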