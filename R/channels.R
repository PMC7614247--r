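#' Decompose the memory into interaction channels
#'
#' The memory function factorizes over pathways subnetwork -> bulk ->
#' subnetwork: expanding the outgoing derivative `dR_b''/dx_s'` inside the
#' prefactor `c` and the incoming derivative `dR_s/dx_b` inside `f0` splits
#' the memory *exactly* into additive channels, identified by quadruples
#' (source species `s'`, outgoing bulk mediator `b''`, incoming bulk mediator
#' `b`, target species `s`). The propagator connecting `b''` to `b` is shared
#' across channels. Channels whose outgoing or incoming derivative is
#' identically zero (absent network edges) are dropped.
#'
#' @param model a `memnet_model`.
#' @param partition a `memnet_partition`.
#' @return a tibble of class `memnet_channels` with columns `channel` (id),
#'   `source`, `out_bulk`, `in_bulk`, `target`; the model and partition ride
#'   along as attributes.
#' @export
decompose_channels <- function(model, partition) {
  stopifnot(inherits(model, "memnet_model"),
            inherits(partition, "memnet_partition"))
  sub <- partition$sub; bulk <- partition$bulk
  out_edges <- edge_present(model, rows = bulk, cols = sub)   # s' -> b''
  in_edges <- edge_present(model, rows = sub, cols = bulk)    # b -> s
  rows <- list()
  for (si in seq_along(sub)) {
    for (bo in seq_along(bulk)) {
      if (!out_edges[bo, si]) next
      for (bi in seq_along(bulk)) {
        for (ti in seq_along(sub)) {
          if (!in_edges[ti, bi]) next
          rows[[length(rows) + 1L]] <- tibble::tibble(
            source = partition$sub_names[si],
            out_bulk = partition$bulk_names[bo],
            in_bulk = partition$bulk_names[bi],
            target = partition$sub_names[ti]
          )
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(source = character(0), out_bulk = character(0),
                   in_bulk = character(0), target = character(0))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(channel = paste0(out$source, ">", out$out_bulk, "~",
                                    out$in_bulk, ">", out$target)),
    out
  )
  attr(out, "model") <- model
  attr(out, "partition") <- partition
  class(out) <- c("memnet_channels", class(out))
  out
}

# is dR_i/dx_j not identically zero? symbolic zero detection plus numeric
# confirmation at deterministic sample states
edge_present <- function(model, rows, cols) {
  n <- length(model$species)
  pts <- 0.25 + 2 * halton_points(5L, n)
  out <- matrix(FALSE, length(rows), length(cols))
  if (!is.null(model$dexpr)) {
    for (i in seq_along(rows)) {
      for (j in seq_along(cols)) {
        e <- model$dexpr[[rows[i], cols[j]]]
        if (is.numeric(e) && length(e) == 1L && e == 0) next
        out[i, j] <- TRUE
      }
    }
  } else {
    for (k in seq_len(nrow(pts))) {
      Jk <- jacobian_full(model, pts[k, ])
      out <- out | (abs(Jk[rows, cols, drop = FALSE]) > 1e-12)
    }
  }
  out
}

#' Per-channel memory contributions at a state and delay
#'
#' Evaluates each channel's additive contribution to the memory
#' `M_target(x^s, tau)`; the contributions sum exactly to the output of
#' [memory_function()].
#'
#' @param channels a `memnet_channels` table from [decompose_channels()].
#' @param xs subnetwork state.
#' @param tau single non-negative delay.
#' @return the channel table with an added `value` column.
#' @export
channel_contributions <- function(channels, xs, tau) {
  stopifnot(inherits(channels, "memnet_channels"))
  model <- attr(channels, "model"); partition <- attr(channels, "partition")
  nb <- length(partition$bulk)
  ing <- memory_ingredients(model, partition, xs)
  pf <- propagate_flow(model, partition, xs, tau)
  G <- matrix(pf$G[1, , ], nb, nb)
  ing_phi <- memory_ingredients(model, partition, pf$flow[1, ])
  Jinv <- solve(ing$J)
  vals <- numeric(nrow(channels))
  for (k in seq_len(nrow(channels))) {
    si <- match(channels$source[k], partition$sub_names)
    bo <- match(channels$out_bulk[k], partition$bulk_names)
    bi <- match(channels$in_bulk[k], partition$bulk_names)
    ti <- match(channels$target[k], partition$sub_names)
    cog <- Jinv[, bo] * ing$A[bo, si] * ing$v[si]
    vals[k] <- ing_phi$B[ti, bi] * drop(G %*% cog)[bi]
  }
  out <- channels
  out$value <- vals
  out
}

# per-outgoing-channel prefactor vectors c^(s',b''): columns of J^{-1}
# scaled by A[b'', s'] v[s']; their sum over outgoing pairs is c
outgoing_prefactors <- function(ing, og_pairs) {
  Jinv <- solve(ing$J)
  vapply(seq_len(nrow(og_pairs)), function(k) {
    Jinv[, og_pairs$bo[k]] * ing$A[og_pairs$bo[k], og_pairs$si[k]] *
      ing$v[og_pairs$si[k]]
  }, numeric(nrow(ing$J)))
}

#' Rank channels by their contribution along a trajectory
#'
#' Carries one auxiliary memory accumulator per outgoing channel along a
#' self-consistent (ZMs) trajectory and scores each channel by the time
#' integral of the absolute value of its contribution to the projected
#' equation (default), normalized so that scores sum to one. The metric is a
#' documented reconstruction; alternatives are the maximum absolute
#' contribution and the signed time integral.
#'
#' @param channels a `memnet_channels` table.
#' @param trajectory a `memnet_trajectory` from [integrate_zms()] on the same
#'   model and partition.
#' @param metric `"integrated_abs"` (default), `"max_abs"`, or
#'   `"integrated_signed"`.
#' @return a tibble of class `memnet_channel_ranking` with `score`
#'   (normalized) and `raw_score` columns, sorted by decreasing score.
#'   If the trajectory rests at a fixed point all raw scores are zero; the
#'   ranking is then flagged with attribute `degenerate = TRUE` and uniform
#'   scores.
#' @export
rank_channels <- function(channels, trajectory,
                          metric = c("integrated_abs", "max_abs",
                                     "integrated_signed")) {
  metric <- match.arg(metric)
  stopifnot(inherits(channels, "memnet_channels"),
            inherits(trajectory, "memnet_trajectory"))
  model <- attr(channels, "model"); partition <- attr(channels, "partition")
  tmodel <- attr(trajectory, "model"); tpart <- attr(trajectory, "partition")
  if (!identical(tmodel$rates, model$rates) ||
      !identical(tmodel$params, model$params) ||
      !identical(tpart$sub, partition$sub)) {
    stop("trajectory was produced on a different model/partition")
  }
  contrib <- channel_contribution_series(channels, trajectory)
  times <- trajectory$time
  raw <- vapply(seq_len(nrow(channels)), function(k) {
    v <- contrib[, k]
    switch(metric,
           integrated_abs = trapz_int(times, abs(v)),
           max_abs = max(abs(v)),
           integrated_signed = trapz_int(times, v))
  }, numeric(1))
  total <- sum(abs(raw))
  degenerate <- total < 1e-12
  score <- if (degenerate) rep(1 / length(raw), length(raw)) else abs(raw) / total
  out <- channels
  out$raw_score <- raw
  out$score <- score
  out <- out[order(-out$score), ]
  class(out) <- unique(c("memnet_channel_ranking", class(out)))
  attr(out, "degenerate") <- degenerate
  attr(out, "metric") <- metric
  out
}

# time series of per-channel contributions to dx^s/dt along a trajectory:
# integrates one auxiliary m-vector per outgoing channel driven by the
# trajectory's dense output, then applies the incoming coupling
channel_contribution_series <- function(channels, trajectory) {
  model <- attr(channels, "model"); partition <- attr(channels, "partition")
  nb <- length(partition$bulk)
  og <- unique(data.frame(
    si = match(channels$source, partition$sub_names),
    bo = match(channels$out_bulk, partition$bulk_names)
  ))
  nog <- nrow(og)
  times <- trajectory$time
  cache <- new.env()
  rhs <- function(t, y, p) {
    xs <- drop(interpolate_trajectory(trajectory, t))
    ing <- memory_ingredients(model, partition, xs, cache = cache)
    Cog <- outgoing_prefactors(ing, og)      # nb x nog
    M <- matrix(y, nb, nog)
    list(as.vector(Cog + ing$Lambda %*% M))
  }
  sol <- deSolve::ode(y = rep(0, nb * nog), times = times, func = rhs,
                      parms = NULL, rtol = 1e-9, atol = 1e-12)
  check_desolve(sol, times)
  Ms <- unname(as.matrix(sol[, -1, drop = FALSE]))
  cache2 <- new.env()
  out <- matrix(0, length(times), nrow(channels))
  for (i in seq_along(times)) {
    xs <- drop(interpolate_trajectory(trajectory, times[i]))
    ing <- memory_ingredients(model, partition, xs, cache = cache2)
    M <- matrix(Ms[i, ], nb, nog)
    for (k in seq_len(nrow(channels))) {
      ogk <- which(og$si == match(channels$source[k], partition$sub_names) &
                   og$bo == match(channels$out_bulk[k], partition$bulk_names))
      bi <- match(channels$in_bulk[k], partition$bulk_names)
      ti <- match(channels$target[k], partition$sub_names)
      out[i, k] <- ing$B[ti, bi] * M[bi, ogk]
    }
  }
  out
}

trapz_int <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Self-consistent integrator with selected channels ablated
#'
#' Returns an integrator identical to [integrate_zms()] except that the
#' memory retains only the kept channels; removed channels contribute no
#' memory, i.e. their pathways are treated as instantaneously at QSS.
#' Keeping all channels reproduces [integrate_zms()] (the per-channel
#' auxiliaries aggregate exactly to the per-bulk-species accumulator);
#' keeping none reproduces [integrate_qss()].
#'
#' @param model a `memnet_model`.
#' @param partition a `memnet_partition`.
#' @param keep a `memnet_channels` subset, a vector of channel id strings,
#'   `"all"`, or `"none"`.
#' @return a function `(xs0, times, rtol = 1e-8, atol = 1e-10)` returning a
#'   `memnet_trajectory` with variant `"zms"`.
#' @export
ablate_channels <- function(model, partition, keep) {
  all_ch <- decompose_channels(model, partition)
  if (identical(keep, "all")) keep <- all_ch
  if (identical(keep, "none")) keep <- all_ch[0, ]
  if (is.character(keep)) {
    unknown <- setdiff(keep, all_ch$channel)
    if (length(unknown)) {
      stop("unknown channel id", if (length(unknown) > 1) "s" else "", ": ",
           paste(unknown, collapse = ", "))
    }
    keep <- all_ch[all_ch$channel %in% keep, ]
  }
  if (!all(keep$channel %in% all_ch$channel)) {
    stop("kept channels must be a subset of the model's channels")
  }
  n_keep <- nrow(keep)
  if (n_keep == nrow(all_ch)) {
    return(function(xs0, times, rtol = 1e-8, atol = 1e-10) {
      integrate_zms(model, partition, xs0, times, rtol = rtol, atol = atol)
    })
  }
  if (n_keep == 0L) {
    return(function(xs0, times, rtol = 1e-8, atol = 1e-10) {
      traj <- integrate_qss(model, partition, xs0, times, rtol = rtol,
                            atol = atol)
      attr(traj, "variant") <- "zms"
      attr(traj, "kept_channels") <- character(0)
      traj
    })
  }

  sub <- partition$sub; bulk <- partition$bulk
  ns <- length(sub); nb <- length(bulk)
  og <- unique(data.frame(
    si = match(keep$source, partition$sub_names),
    bo = match(keep$out_bulk, partition$bulk_names)
  ))
  nog <- nrow(og)
  # incoming mask per outgoing channel: mask[ti, bi, ogk]
  mask <- array(0, c(ns, nb, nog))
  for (k in seq_len(nrow(keep))) {
    ogk <- which(og$si == match(keep$source[k], partition$sub_names) &
                 og$bo == match(keep$out_bulk[k], partition$bulk_names))
    bi <- match(keep$in_bulk[k], partition$bulk_names)
    ti <- match(keep$target[k], partition$sub_names)
    mask[ti, bi, ogk] <- 1
  }

  function(xs0, times, rtol = 1e-8, atol = 1e-10) {
    times <- expand_times(times)
    cache <- new.env()
    rhs <- function(t, y, p) {
      xs <- y[seq_len(ns)]
      M <- matrix(y[-seq_len(ns)], nb, nog)
      ing <- memory_ingredients(model, partition, xs, cache = cache)
      mem <- numeric(ns)
      for (ogk in seq_len(nog)) {
        mem <- mem + drop((ing$B * matrix(mask[, , ogk], ns, nb)) %*% M[, ogk])
      }
      Cog <- outgoing_prefactors(ing, og)
      dM <- Cog + ing$Lambda %*% M
      list(c(unname(ing$v + mem), as.vector(dM)))
    }
    sol <- run_desolve(rhs, c(xs0, rep(0, nb * nog)), times, rtol, atol)
    traj <- new_trajectory(sol$times, sol$states[, seq_len(ns), drop = FALSE],
                           sol$derivs[, seq_len(ns), drop = FALSE],
                           species = partition$sub_names, variant = "zms",
                           model = model, partition = partition,
                           aux = sol$states[, -seq_len(ns), drop = FALSE],
                           aux_derivs = sol$derivs[, -seq_len(ns), drop = FALSE])
    attr(traj, "kept_channels") <- keep$channel
    traj
  }
}

#' Write a ranking's dominant channels as a Graphviz dot file
#'
#' Aggregates channel scores to sender -> receiver arcs (source subnetwork
#' species to target subnetwork species) and writes a directed graph with
#' edge weights proportional to the aggregated scores.
#'
#' @param ranking a `memnet_channel_ranking`.
#' @param file output path.
#' @param top_k keep the `top_k` highest-scoring arcs (default all).
#' @return the dot text, invisibly.
#' @export
channel_graph_dot <- function(ranking, file, top_k = Inf) {
  stopifnot(inherits(ranking, "memnet_channel_ranking"))
  arcs <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ranking), .data$source, .data$target),
    score = sum(.data$score), .groups = "drop"
  )
  arcs <- arcs[order(-arcs$score), ]
  if (is.finite(top_k)) arcs <- utils::head(arcs, top_k)
  lines <- c(
    "digraph memory_channels {",
    sprintf('  "%s" -> "%s" [label="%.3f", penwidth=%.2f];',
            arcs$source, arcs$target, arcs$score,
            0.5 + 4 * arcs$score / max(arcs$score)),
    "}"
  )
  writeLines(lines, file)
  invisible(paste(lines, collapse = "\n"))
}
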