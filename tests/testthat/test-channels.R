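test_that("channel sums reproduce the total memory at random states", {
  cases <- list(
    list(m = bistable2, p = bistable2_part, lo = 0.1, hi = 5),
    list(m = neural4, p = neural4_part, lo = 0.1, hi = 3),
    list(m = linbulk, p = linbulk_part, lo = 0.2, hi = 3)
  )
  for (cs in cases) {
    ch <- decompose_channels(cs$m, cs$p)
    states <- sample_states(10, length(cs$p$sub), cs$lo, cs$hi)
    taus <- withr::with_seed(7, stats::runif(10, 0, 3))
    for (k in seq_len(nrow(states))) {
      cc <- channel_contributions(ch, states[k, ], taus[k])
      mf <- memory_function(cs$m, cs$p, states[k, ], taus[k])
      tot <- vapply(cs$p$sub_names, function(s) {
        sum(cc$value[cc$target == s])
      }, numeric(1))
      expect_lt(max(abs(tot - unlist(mf[1, cs$p$sub_names]))), 1e-10)
    }
  }
})

test_that("the two-node switch has exactly one channel equal to its memory", {
  ch <- decompose_channels(bistable2, bistable2_part)
  expect_equal(nrow(ch), 1L)
  expect_identical(ch$channel, "x1>x2~x2>x1")
  cc <- channel_contributions(ch, 1.5, 0.7)
  mf <- memory_function(bistable2, bistable2_part, 1.5, 0.7)
  expect_equal(cc$value, mf$x1, tolerance = 1e-12)
})

test_that("channel list mirrors the network's edge structure", {
  ch <- decompose_channels(neural4, neural4_part)
  # expected from the configured topology: outgoing edges are every
  # subnetwork species acting on every bulk species; incoming edges are
  # Irx3 -> both, Pax6 -> Nkx2.2 only (Pax6 does not regulate Olig2)
  out_edges <- expand.grid(source = c("Nkx2.2", "Olig2"),
                           out_bulk = c("Irx3", "Pax6"),
                           stringsAsFactors = FALSE)
  in_edges <- data.frame(in_bulk = c("Irx3", "Irx3", "Pax6"),
                         target = c("Nkx2.2", "Olig2", "Nkx2.2"))
  expected <- merge(out_edges, in_edges)
  expect_equal(nrow(ch), nrow(expected))    # 4 x 3 = 12 channels
  got <- ch[, c("source", "out_bulk", "in_bulk", "target")]
  expect_setequal(
    do.call(paste, as.list(got)),
    do.call(paste, expected[, c("source", "out_bulk", "in_bulk", "target")])
  )
  expect_false(any(ch$in_bulk == "Pax6" & ch$target == "Olig2"))
})

test_that("single-channel rankings score 1 and resting rankings are degenerate", {
  ch <- decompose_channels(bistable2, bistable2_part)
  times <- seq(0, 20, length.out = 101)
  tr <- integrate_zms(bistable2, bistable2_part, 1.4, times)
  rk <- rank_channels(ch, tr)
  expect_equal(rk$score, 1)
  expect_false(attr(rk, "degenerate"))
  # trajectory resting at a fixed point: all raw contributions vanish
  fp <- find_fixed_points(bistable2, c(0, 10), partition = bistable2_part,
                          system = "qss")
  tr0 <- integrate_zms(bistable2, bistable2_part, max(fp$x1), times)
  rk0 <- rank_channels(ch, tr0)
  expect_true(attr(rk0, "degenerate"))
  expect_lt(max(abs(rk0$raw_score)), 1e-10)
})

test_that("duplicating a bulk species splits its channel scores in half", {
  # split x2 of the two-node switch into two identical half-strength species
  dup <- network_model(
    c("x1", "y", "z"),
    c(x1 = "a/(1 + (y + z)^n) - x1",
      y = "0.5*a/(1 + x1^n) - y",
      z = "0.5*a/(1 + x1^n) - z"),
    params = c(a = 6, n = 3)
  )
  pd <- subnetwork_partition(dup, "x1")
  ch <- decompose_channels(dup, pd)
  expect_equal(nrow(ch), 4L)     # 2 outgoing x 2 incoming
  times <- seq(0, 20, length.out = 101)
  tr <- integrate_zms(dup, pd, 1.4, times)
  rk <- rank_channels(ch, tr)
  by_mediator <- tapply(rk$score, rk$out_bulk, sum)
  expect_equal(unname(by_mediator["y"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(by_mediator["z"]), 0.5, tolerance = 1e-8)
  # and the duplicated system still reproduces the original subnetwork flow
  orig <- integrate_zms(bistable2, bistable2_part, 1.4, times)
  expect_lt(max(abs(tr$x1 - orig$x1)), 1e-6)
})

test_that("keep-all ablation is the ZMs integrator, keep-none is QSS", {
  times <- seq(0, 25, length.out = 126)
  keep_all <- ablate_channels(neural4, neural4_part, "all")
  zms <- integrate_zms(neural4, neural4_part, c(0.2, 0.1), times)
  abl <- keep_all(c(0.2, 0.1), times)
  expect_lt(max(abs(as.matrix(abl[, neural4_part$sub_names]) -
                    as.matrix(zms[, neural4_part$sub_names]))), 1e-12)
  keep_none <- ablate_channels(neural4, neural4_part, "none")
  qss <- integrate_qss(neural4, neural4_part, c(0.2, 0.1), times)
  abn <- keep_none(c(0.2, 0.1), times)
  expect_lt(max(abs(as.matrix(abn[, neural4_part$sub_names]) -
                    as.matrix(qss[, neural4_part$sub_names]))), 1e-12)
  expect_error(ablate_channels(neural4, neural4_part, "no>such~chan>nel"),
               "unknown channel")
})

test_that("keeping the dominant channels tracks ZMs better than QSS does", {
  ch <- decompose_channels(neural4, neural4_part)
  times <- seq(0, 25, length.out = 126)
  xs0 <- c(0.05, 0.05)
  zms <- integrate_zms(neural4, neural4_part, xs0, times)
  rk <- rank_channels(ch, zms)
  top <- rk[seq_len(4), ]
  abl <- ablate_channels(neural4, neural4_part, top$channel)(xs0, times)
  qss <- integrate_qss(neural4, neural4_part, xs0, times)
  dev <- function(tr) max(abs(as.matrix(tr[, neural4_part$sub_names]) -
                              as.matrix(zms[, neural4_part$sub_names])))
  expect_lt(dev(abl), dev(qss))
})
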