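#' Integrate any system variant from a subnetwork initial condition
#'
#' Dispatcher used by the phase-space analyses: `"full"` initializes the bulk
#' at QSS and integrates the complete network, `"qss"`, `"zmn"` and `"zms"`
#' integrate the corresponding reduced system. The returned trajectory always
#' exposes the subnetwork species (the full variant's bulk columns are kept).
#'
#' @inheritParams integrate_qss
#' @param variant one of `"full"`, `"qss"`, `"zmn"`, `"zms"`.
#' @param ... passed to the underlying integrator.
#' @export
variant_trajectory <- function(model, partition, variant, xs0, times, ...) {
  switch(variant,
    full = integrate_full(model, xs0, times, partition = partition, ...),
    qss = integrate_qss(model, partition, xs0, times, ...),
    zms = integrate_zms(model, partition, xs0, times, ...),
    zmn = integrate_zmn(model, partition, xs0, max(times), ...),
    stop("unknown variant '", variant, "'")
  )
}

sub_states <- function(traj, partition) {
  as.matrix(traj[, partition$sub_names, drop = FALSE])
}

# integrate from xs0 until within match_tol of an attractor (rows of
# `attractors`, subnetwork coordinates) or t_max; returns label + time
label_point <- function(model, partition, variant, xs0, attractors,
                        match_tol = 1e-3, t_max = 500, chunk = 25,
                        rtol = 1e-8, atol = 1e-10) {
  t0 <- 0
  state <- xs0
  full <- variant == "full"
  if (full) {
    x <- numeric(length(model$species))
    x[partition$sub] <- xs0
    x[partition$bulk] <- solve_qss(model, partition, xs0)
    state <- x
  }
  if (variant == "zmn") {
    # history-integral variant cannot be resumed chunk-wise; integrate once
    traj <- integrate_zmn(model, partition, xs0, t_max)
    xsub <- sub_states(traj, partition)
    d <- apply(xsub, 1, function(s) {
      min(apply(attractors, 1, function(a) max(abs(a - s))))
    })
    hit <- which(d <= match_tol)
    if (length(hit)) {
      i <- hit[1]
      lab <- which.min(apply(attractors, 1,
                             function(a) max(abs(a - xsub[i, ]))))
      return(list(label = lab, t = traj$time[i], resolved = TRUE))
    }
    return(list(label = NA_integer_, t = t_max, resolved = FALSE))
  }
  while (t0 < t_max) {
    tend <- min(chunk, t_max - t0)
    times <- seq(0, tend, length.out = 41L)
    traj <- if (full) {
      integrate_full(model, state, times, rtol = rtol, atol = atol)
    } else {
      variant_trajectory(model, partition, variant, state, times,
                         rtol = rtol, atol = atol)
    }
    xsub <- sub_states(traj, partition)
    final <- xsub[nrow(xsub), ]
    d <- apply(attractors, 1, function(a) max(abs(a - final)))
    if (min(d) <= match_tol) {
      return(list(label = which.min(d), t = t0 + tend, resolved = TRUE))
    }
    lastrow <- as.matrix(traj[nrow(traj), attr(traj, "species"), drop = FALSE])
    state <- drop(lastrow)
    if (!full && attr(traj, "variant") == "zms" && !is.null(attr(traj, "aux"))) {
      # ZMs chunks must carry the memory accumulator across restarts
      state <- c(state, attr(traj, "aux")[nrow(traj), ])
    }
    t0 <- t0 + tend
  }
  list(label = NA_integer_, t = t_max, resolved = FALSE)
}

#' Basin-of-attraction map on a subnetwork grid
#'
#' Labels every node of an initial-condition lattice by the stable attractor
#' its trajectory reaches, per system variant. The attractor catalogue is the
#' set of stable fixed points of the full system projected onto the
#' subnetwork (all variants share these fixed points). Full-variant runs
#' initialize the bulk at QSS. Nodes not within `match_tol` of any attractor
#' by `t_max` are flagged unresolved (`NA` label), never silently labeled.
#' The whole procedure is deterministic.
#'
#' @inheritParams integrate_qss
#' @param grid named list of coordinate vectors, one per subnetwork species
#'   (e.g. `list(x1 = seq(0, 4, length.out = 21), x2 = ...)`).
#' @param variants which system variants to map.
#' @param attractors optional matrix of stable attractor locations in
#'   subnetwork coordinates (one per row); computed from
#'   [find_fixed_points()] on the full system over the grid box when omitted.
#' @param match_tol attractor matching tolerance (absolute, default 1e-3).
#' @param t_max integration horizon per node.
#' @param rtol,atol integrator tolerances.
#' @return a tibble of class `memnet_basin_map`: grid coordinates, `variant`,
#'   `label` (attractor row index, `NA` if unresolved), `t_converged`.
#'   The attractor catalogue is in `attr(, "attractors")`.
#' @export
basin_map <- function(model, partition, grid,
                      variants = c("full", "qss", "zms"),
                      attractors = NULL, match_tol = 1e-3, t_max = 500,
                      rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(partition, "memnet_partition"))
  ns <- length(partition$sub)
  stopifnot(length(grid) == ns)
  if (is.null(names(grid))) names(grid) <- partition$sub_names
  grid <- grid[partition$sub_names]
  if (is.null(attractors)) {
    lo <- vapply(grid, min, numeric(1)); hi <- vapply(grid, max, numeric(1))
    fullbox <- full_box_from_sub(model, partition, lo, hi)
    fp <- find_fixed_points(model, fullbox, system = "full", n_starts = 128L)
    attractors <- stable_points(fp)[, partition$sub_names, drop = FALSE]
  }
  if (!nrow(attractors)) stop("no stable attractors found")
  nodes <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (variant in variants) {
    labs <- integer(nrow(nodes)); tcs <- numeric(nrow(nodes))
    res <- logical(nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      r <- label_point(model, partition, variant, nodes[i, ], attractors,
                       match_tol = match_tol, t_max = t_max,
                       rtol = rtol, atol = atol)
      labs[i] <- r$label; tcs[i] <- r$t; res[i] <- r$resolved
    }
    out[[variant]] <- dplyr::bind_cols(
      tibble::as_tibble(nodes),
      tibble::tibble(variant = variant, label = labs, t_converged = tcs,
                     resolved = res)
    )
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("memnet_basin_map", class(out))
  attr(out, "attractors") <- attractors
  out
}

full_box_from_sub <- function(model, partition, lo, hi) {
  n <- length(model$species)
  box <- matrix(0, 2, n)
  box[1, partition$sub] <- lo
  box[2, partition$sub] <- hi
  if (length(partition$bulk)) {
    box[2, partition$bulk] <- bulk_scale_box(model, partition)
  }
  box
}

#' Refine a basin boundary point by bisection
#'
#' Bisects along the segment between two initial conditions with different
#' basin labels until the bracket is shorter than the requested number of
#' steps allows.
#'
#' @inheritParams basin_map
#' @param variant system variant.
#' @param p1,p2 subnetwork states with different labels.
#' @param steps bisection steps (default 20).
#' @return the midpoint of the final bracket (subnetwork coordinates).
#' @export
refine_separatrix <- function(model, partition, variant, p1, p2, attractors,
                              steps = 20L, match_tol = 1e-3, t_max = 500) {
  l1 <- label_point(model, partition, variant, p1, attractors,
                    match_tol, t_max)$label
  l2 <- label_point(model, partition, variant, p2, attractors,
                    match_tol, t_max)$label
  if (is.na(l1) || is.na(l2) || l1 == l2) {
    stop("p1 and p2 must resolve to different attractors")
  }
  for (i in seq_len(steps)) {
    mid <- (p1 + p2) / 2
    lm <- label_point(model, partition, variant, mid, attractors,
                      match_tol, t_max)$label
    if (is.na(lm)) break
    if (lm == l1) p1 <- mid else p2 <- mid
  }
  (p1 + p2) / 2
}

#' Classify a trajectory as converged, damped- or sustained-oscillatory
#'
#' Works on the dense output after discarding an initial transient window.
#' The post-transient signal is split into `min_periods + 1` consecutive time
#' blocks and the oscillation envelope is measured as the peak-to-trough
#' amplitude per block (robust against limit cycles with secondary extrema
#' within one period). The verdict is `sustained-oscillatory` when every
#' block contains at least one local maximum and the last `min_periods`
#' successive block-amplitude ratios lie within `sustained_tol` of one;
#' `damped-oscillatory` when the signal oscillates with a decaying envelope;
#' `converged` when the trailing signal is flat; `inconclusive` when there
#' are too few extrema to decide (fewer than 8 in the whole window and no
#' convergence).
#'
#' @param traj a `memnet_trajectory`.
#' @param observable species name or index (within the trajectory columns).
#' @param transient_frac fraction of the time window discarded (default 0.3).
#' @param sustained_tol tolerance on the envelope decay ratio (0.01).
#' @param min_periods successive envelope ratios required for a sustained
#'   verdict (each block spans at least one oscillation period).
#' @param n_dense dense sampling resolution.
#' @return one-row tibble: `verdict`, `period` (mean spacing of local
#'   maxima), `decay_ratio` (mean trailing envelope ratio), `n_peaks`.
#' @export
classify_oscillation <- function(traj, observable = 1,
                                 transient_frac = 0.3, sustained_tol = 0.01,
                                 min_periods = 5L, n_dense = 4000L) {
  species <- attr(traj, "species")
  if (is.character(observable)) observable <- match(observable, species)
  t_all <- seq(traj$time[1], max(traj$time), length.out = n_dense)
  y_all <- interpolate_trajectory(traj, t_all)[, observable]
  scale <- diff(range(y_all))
  t0 <- max(traj$time) * transient_frac
  sel <- t_all >= t0
  t <- t_all[sel]; y <- y_all[sel]

  tail_sel <- t >= (max(t) - 0.15 * (max(t) - min(t)))
  tail_amp <- diff(range(y[tail_sel]))
  d <- diff(y)
  imax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  imin <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  period <- if (length(imax) >= 2L) mean(diff(t[imax])) else NA_real_
  result <- function(verdict, ratio = NA_real_) {
    tibble::tibble(verdict = verdict, period = period, decay_ratio = ratio,
                   n_peaks = length(imax))
  }
  flat <- tail_amp <= max(1e-9, 1e-6 * scale)
  if (length(imax) < 2L) {
    if (flat || length(imax) + length(imin) < 2L) {
      period <- NA_real_
      return(result("converged"))
    }
    return(result("inconclusive"))
  }
  if (flat) return(result("converged"))

  nblock <- min_periods + 1L
  breaks <- seq(min(t), max(t), length.out = nblock + 1L)
  block <- findInterval(t, breaks, rightmost.closed = TRUE)
  amps <- vapply(seq_len(nblock), function(b) {
    yy <- y[block == b]
    if (length(yy) < 3L) return(NA_real_)
    diff(range(yy))
  }, numeric(1))
  has_max <- vapply(seq_len(nblock), function(b) {
    any(t[imax] >= breaks[b] & t[imax] <= breaks[b + 1L])
  }, logical(1))
  ratios <- amps[-1] / amps[-nblock]
  # blocks span many periods; the tolerance is defined per oscillation
  # period, so normalise each block ratio to a per-period decay ratio
  block_len <- diff(breaks)[1]
  pp <- ratios^(period / block_len)
  if (all(has_max) && all(is.finite(pp)) &&
      all(abs(pp - 1) <= sustained_tol)) {
    return(result("sustained-oscillatory", mean(pp)))
  }
  if (length(imax) + length(imin) < 8L) return(result("inconclusive"))
  result("damped-oscillatory", mean(pp[is.finite(pp)]))
}

#' Two-parameter Hopf-boundary scan of the cyclic repression circuit
#'
#' Scans the (a, n) parameter plane of the three-species repressilator
#' (`dx_j/dt = a/(1 + x_{j-1}^n) - x_j`, bulk `x3`), integrating each variant
#' from a fixed off-attractor initial condition and classifying the resulting
#' trajectory. For the full and QSS variants the simulation verdict can be
#' cross-checked against linear stability of the symmetric fixed point: the
#' full system undergoes a Hopf bifurcation where the complex eigenvalue
#' pair `-1 + b e^{+-2 pi i/3}` (with `b` the repression slope at the
#' symmetric point) crosses the imaginary axis.
#'
#' @param a_values,n_values grid values of the production strength `a` and
#'   Hill exponent `n`.
#' @param variants system variants to classify.
#' @param t_end trajectory horizon per grid point.
#' @param marginal_band grid points whose symmetric-point eigenvalue real
#'   part is within this band are flagged marginal (simulation-based
#'   classification is unreliable exactly at the bifurcation).
#' @param rtol,atol integrator tolerances.
#' @return a tibble of class `memnet_hopf_scan`: `a`, `n`, `variant`,
#'   `verdict`, `sustained` (logical), `period`, `eigen_re` (full-system
#'   leading eigenvalue real part at the symmetric fixed point),
#'   `eigen_sustained`, `marginal`.
#' @export
hopf_scan <- function(a_values, n_values,
                      variants = c("full", "qss", "zms"),
                      t_end = 150, marginal_band = 0.02,
                      rtol = 1e-8, atol = 1e-10) {
  rows <- list()
  for (n in n_values) {
    for (a in a_values) {
      model <- fixture_model("repressilator", a = a, n = n)
      partition <- default_partition(model)
      xstar <- stats::uniroot(function(x) x * (1 + x^n) - a,
                              lower = 0, upper = max(a, 1),
                              tol = 1e-12)$root
      b <- -a * n * xstar^(n - 1) / (1 + xstar^n)^2
      eigen_re <- -1 - b / 2          # real part of the complex pair
      xs0 <- xstar * c(1.3, 0.8)
      for (variant in variants) {
        traj <- variant_trajectory(model, partition, variant, xs0, t_end,
                                   rtol = rtol, atol = atol)
        cls <- classify_oscillation(traj, observable = 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          a = a, n = n, variant = variant,
          verdict = cls$verdict,
          sustained = cls$verdict == "sustained-oscillatory",
          period = cls$period,
          eigen_re = eigen_re,
          eigen_sustained = eigen_re > 0,
          marginal = abs(eigen_re) < marginal_band
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("memnet_hopf_scan", class(out))
  out
}

#' Boundary of the sustained-oscillation region of a Hopf scan
#'
#' For each scanned Hill exponent `n`, the smallest `a` classified sustained
#' (as a grid row index and value); `NA` where the variant has no sustained
#' point in that column.
#'
#' @param scan a `memnet_hopf_scan`.
#' @param variant variant whose boundary to extract.
#' @return tibble with `n`, `a_boundary`, `row` (index into the sorted
#'   a-grid).
#' @export
hopf_boundary <- function(scan, variant) {
  stopifnot(inherits(scan, "memnet_hopf_scan"))
  sc <- scan[scan$variant == variant, ]
  a_grid <- sort(unique(sc$a))
  dplyr::bind_rows(lapply(sort(unique(sc$n)), function(nv) {
    col <- sc[sc$n == nv, ]
    col <- col[order(col$a), ]
    idx <- which(col$sustained)
    tibble::tibble(
      n = nv,
      a_boundary = if (length(idx)) col$a[min(idx)] else NA_real_,
      row = if (length(idx)) match(col$a[min(idx)], a_grid) else NA_integer_
    )
  }))
}

#' Memory-amplitude field on a subnetwork grid
#'
#' Evaluates the zero-delay memory `M(x^s, 0)` per subnetwork species on a
#' lattice and extracts the zero-level contour (for two-dimensional
#' subnetworks): the curve across which the instantaneous memory changes
#' sign.
#'
#' @inheritParams basin_map
#' @return a tibble of class `memnet_memory_map` with the grid coordinates
#'   and one amplitude column `M_<species>` per subnetwork species; for 2D
#'   grids the zero contours are in `attr(, "contours")` (a named list of
#'   tibbles with columns `x`, `y`, `piece`).
#' @export
memory_amplitude_map <- function(model, partition, grid) {
  ns <- length(partition$sub)
  stopifnot(length(grid) == ns)
  if (is.null(names(grid))) names(grid) <- partition$sub_names
  grid <- grid[partition$sub_names]
  nodes <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
  cache <- new.env()
  vals <- vapply(seq_len(nrow(nodes)), function(i) {
    memory_amplitude(model, partition, nodes[i, ], cache = cache)
  }, numeric(ns))
  amp <- if (ns == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(amp) <- paste0("M_", partition$sub_names)
  out <- dplyr::bind_cols(tibble::as_tibble(nodes), tibble::as_tibble(amp))
  class(out) <- c("memnet_memory_map", class(out))
  if (ns == 2L) {
    contours <- lapply(seq_len(ns), function(s) {
      z <- matrix(amp[, s], length(grid[[1]]), length(grid[[2]]))
      cl <- grDevices::contourLines(grid[[1]], grid[[2]], z, levels = 0)
      if (!length(cl)) return(tibble::tibble(x = numeric(0), y = numeric(0),
                                             piece = integer(0)))
      dplyr::bind_rows(lapply(seq_along(cl), function(p) {
        tibble::tibble(x = cl[[p]]$x, y = cl[[p]]$y, piece = p)
      }))
    })
    names(contours) <- partition$sub_names
    attr(out, "contours") <- contours
  }
  out
}
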