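#' @importFrom tibble tibble as_tibble
NULL

# trajectory constructor: a tibble (time + species columns) carrying the
# integrated states, their time derivatives (for dense cubic-Hermite
# interpolation) and any auxiliary components in attributes
new_trajectory <- function(times, states, derivs, species, variant,
                           model = NULL, partition = NULL,
                           aux = NULL, aux_derivs = NULL, aux_names = NULL) {
  states <- matrix(states, nrow = length(times),
                   dimnames = list(NULL, species))
  out <- dplyr::bind_cols(tibble::tibble(time = times),
                          tibble::as_tibble(states))
  class(out) <- c("memnet_trajectory", class(out))
  attr(out, "derivs") <- matrix(derivs, nrow = length(times))
  attr(out, "variant") <- variant
  attr(out, "species") <- species
  attr(out, "model") <- model
  attr(out, "partition") <- partition
  if (!is.null(aux)) {
    attr(out, "aux") <- matrix(aux, nrow = length(times),
                               dimnames = list(NULL, aux_names))
    attr(out, "aux_derivs") <- matrix(aux_derivs, nrow = length(times))
  }
  out
}

#' Which reduction produced a trajectory
#' @param traj a `memnet_trajectory`.
#' @return one of `"full"`, `"qss"`, `"zmn"`, `"zms"`.
#' @export
trajectory_variant <- function(traj) attr(traj, "variant")

#' Dense evaluation of a trajectory
#'
#' Piecewise cubic Hermite interpolation using the stored states and their
#' exact time derivatives (the ODE right-hand side at the grid nodes); at the
#' grid times it returns the stored states exactly.
#'
#' @param traj a `memnet_trajectory`.
#' @param t times within the trajectory's range.
#' @return matrix with one interpolated state per row (species columns).
#' @export
interpolate_trajectory <- function(traj, t) {
  times <- traj$time
  species <- attr(traj, "species")
  states <- as.matrix(traj[, species, drop = FALSE])
  derivs <- attr(traj, "derivs")[, seq_along(species), drop = FALSE]
  hermite_eval(times, states, derivs, t)
}

# vectorised cubic Hermite interpolation; columns interpolated independently.
# Times are clamped to the stored range: adaptive solvers probe right-hand
# sides slightly beyond the final output time when a trajectory drives
# another ODE.
hermite_eval <- function(times, states, derivs, t) {
  t <- pmin(pmax(t, times[1]), times[length(times)])
  i <- findInterval(t, times, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(times) - 1L)
  h <- times[i + 1L] - times[i]
  s <- (t - times[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  out <- h00 * states[i, , drop = FALSE] +
    (h * h10) * derivs[i, , drop = FALSE] +
    h01 * states[i + 1L, , drop = FALSE] +
    (h * h11) * derivs[i + 1L, , drop = FALSE]
  # exact at grid nodes by construction; enforce against rounding of s
  exact <- match(t, times)
  hit <- which(!is.na(exact))
  if (length(hit)) out[hit, ] <- states[exact[hit], , drop = FALSE]
  colnames(out) <- colnames(states)
  out
}

run_desolve <- function(rhs, y0, times, rtol, atol, method = "lsoda") {
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  check_desolve(sol, times)
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  derivs <- t(vapply(seq_along(times), function(k) {
    unlist(rhs(times[k], states[k, ], NULL)[[1]])
  }, numeric(length(y0))))
  list(times = times, states = states, derivs = matrix(derivs, nrow = length(times)))
}

check_desolve <- function(sol, times) {
  if (nrow(sol) < length(times)) {
    stop("integration failed at t = ", format(sol[nrow(sol), 1], digits = 6),
         " (of ", format(times[length(times)], digits = 6), ")")
  }
  invisible(sol)
}

#' Integrate the full (unreduced) network
#'
#' @param model a `memnet_model`.
#' @param x0 full-dimensional initial state; or, if `partition` is given and
#'   `x0` has subnetwork dimension, the bulk is initialized at its QSS value
#'   `x^b*(x^s(0))`.
#' @param times output time grid starting at 0, or a single end time.
#' @param partition optional `memnet_partition` (for bulk-at-QSS
#'   initialization).
#' @param rtol,atol integrator tolerances.
#' @return a `memnet_trajectory` over all species.
#' @export
integrate_full <- function(model, x0, times, partition = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "memnet_model"))
  times <- expand_times(times)
  n <- length(model$species)
  if (length(x0) != n) {
    if (is.null(partition) || length(x0) != length(partition$sub)) {
      stop("x0 must be full-dimensional, or subnetwork-dimensional with a ",
           "partition for bulk-at-QSS initialization")
    }
    xfull <- numeric(n)
    xfull[partition$sub] <- x0
    xfull[partition$bulk] <- solve_qss(model, partition, x0)
    x0 <- xfull
  }
  rhs <- function(t, y, p) list(unname(evaluate_rates(model, y)))
  sol <- run_desolve(rhs, x0, times, rtol, atol)
  new_trajectory(sol$times, sol$states, sol$derivs, species = model$species,
                 variant = "full", model = model, partition = partition)
}

#' Integrate the QSS-reduced subnetwork
#'
#' Memoryless reduction `d x^s/dt = v(x^s)`. With an empty bulk this is the
#' full system.
#'
#' @inheritParams integrate_full
#' @param partition a `memnet_partition`.
#' @param xs0 initial subnetwork state.
#' @export
integrate_qss <- function(model, partition, xs0, times,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(partition, "memnet_partition"))
  if (!length(partition$bulk)) {
    traj <- integrate_full(model, xs0, times, rtol = rtol, atol = atol)
    attr(traj, "variant") <- "qss"
    return(traj)
  }
  traj <- qss_flow(model, partition, xs0, times, rtol = rtol, atol = atol)
  traj
}

#' Integrate the self-consistent (ZMs) reduced system
#'
#' Evolves the subnetwork together with one auxiliary memory accumulator per
#' bulk species:
#' `d x^s/dt = v(x^s) + B(x^s) m`, `d m/dt = c(x^s) + Lambda(x^s) m`,
#' `m(0) = 0`. The auxiliary `m` tracks the accumulated bulk deviation from
#' QSS induced by the subnetwork's own history, propagated along the actual
#' (memory-corrected) trajectory; this evaluates the self-consistent memory
#' integral exactly, without storing history. The reduction is exact whenever
#' the rates depend at most linearly on the bulk species.
#'
#' @inheritParams integrate_qss
#' @return a `memnet_trajectory` over the subnetwork species; the auxiliary
#'   `m` components are available via `attr(x, "aux")`.
#' @export
integrate_zms <- function(model, partition, xs0, times,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(partition, "memnet_partition"))
  if (!length(partition$bulk)) {
    traj <- integrate_full(model, xs0, times, rtol = rtol, atol = atol)
    attr(traj, "variant") <- "zms"
    return(traj)
  }
  times <- expand_times(times)
  ns <- length(partition$sub); nb <- length(partition$bulk)
  # xs0 may carry an initial memory accumulator (length ns + nb), used when
  # resuming a ZMs run; a plain subnetwork state starts from m = 0
  y0 <- if (length(xs0) == ns + nb) xs0 else c(xs0, rep(0, nb))
  stopifnot(length(y0) == ns + nb)
  cache <- new.env()
  rhs <- function(t, y, p) {
    xs <- y[seq_len(ns)]
    m <- y[-seq_len(ns)]
    ing <- memory_ingredients(model, partition, xs, cache = cache)
    dxs <- ing$v + drop(ing$B %*% m)
    dm <- ing$c + drop(ing$Lambda %*% m)
    list(c(unname(dxs), unname(dm)))
  }
  sol <- run_desolve(rhs, y0, times, rtol, atol)
  new_trajectory(sol$times, sol$states[, seq_len(ns), drop = FALSE],
                 sol$derivs[, seq_len(ns), drop = FALSE],
                 species = partition$sub_names, variant = "zms",
                 model = model, partition = partition,
                 aux = sol$states[, -seq_len(ns), drop = FALSE],
                 aux_derivs = sol$derivs[, -seq_len(ns), drop = FALSE],
                 aux_names = paste0("m_", partition$bulk_names))
}

#' Integrate the nonlinear-memory (ZMn) reduced system
#'
#' Solves the projected integro-differential equation
#' `d x^s/dt = v(x^s(t)) + int_0^t M(x^s(t'), t - t') dt'`, with the memory
#' function of [memory_function()]. The history integral is discretized on a
#' fixed grid of step `h` with trapezoidal weights; for each history node the
#' QSS-flow position and propagator matrix are advanced in the delay variable
#' as `t` grows (one batched Runge-Kutta step per node per outer step), so
#' the per-step cost is linear in the history length. The outer stepper is
#' Heun's method, matching the trapezoid's second order; halving `h` changes
#' the trajectory by O(h^2). Nodes whose propagator norm has decayed below
#' `trunc_tol` (relative) stop contributing and are no longer advanced.
#'
#' @inheritParams integrate_qss
#' @param t_end end time; output is on the history grid `seq(0, t_end, h)`.
#' @param h history/outer step size (default `t_end/800`).
#' @param trunc_tol relative propagator-norm truncation threshold.
#' @return a `memnet_trajectory` over the subnetwork species.
#' @export
integrate_zmn <- function(model, partition, xs0, t_end, h = t_end / 800,
                          trunc_tol = 1e-12) {
  stopifnot(inherits(partition, "memnet_partition"))
  ns <- length(partition$sub); nb <- length(partition$bulk)
  if (nb == 0L) {
    traj <- integrate_full(model, xs0, seq(0, t_end, by = h))
    attr(traj, "variant") <- "zmn"
    return(traj)
  }
  nsteps <- max(2L, ceiling(t_end / h))
  h <- t_end / nsteps
  times <- seq(0, t_end, length.out = nsteps + 1L)

  XS <- matrix(0, nsteps + 1L, ns)       # outer solution
  PHI <- matrix(0, nsteps + 1L, ns)      # RHS at nodes (dense output)
  XS[1, ] <- xs0

  # history auxiliaries, one row per node j: flow position Y[j,],
  # propagator G[j,,], prefactor Cm[j,], bulk warm start XB[j,]
  Y <- matrix(xs0, 1L, ns)
  G <- array(diag(nb), c(1L, nb, nb))
  ing0 <- memory_ingredients(model, partition, xs0)
  Cm <- matrix(ing0$c, 1L, nb)
  XB <- matrix(ing0$xb, 1L, nb)
  active <- TRUE

  # memory integrand at the current outer time for all nodes
  node_memory <- function(Y, G, Cm, XB, active) {
    M <- matrix(0, nrow(Y), ns)
    if (!any(active)) return(M)
    bi <- batch_ingredients(model, partition, Y[active, , drop = FALSE],
                            XB[active, , drop = FALSE])
    idx <- which(active)
    for (k in seq_along(idx)) {
      j <- idx[k]
      Bk <- matrix(bi$B[k, , ], ns, nb)
      M[j, ] <- Bk %*% (matrix(G[j, , ], nb, nb) %*% Cm[j, ])
    }
    M
  }

  trapz_memory <- function(M) {
    nr <- nrow(M)
    if (nr < 2L) return(numeric(ns))
    w <- rep(h, nr); w[1] <- h / 2; w[nr] <- h / 2
    drop(crossprod(M, w))
  }

  # advance all active auxiliaries by h in the delay variable (one RK4 step
  # on dy/dtau = v(y), dG/dtau = Lambda(y) G, batched over nodes)
  advance_aux <- function(Y, G, XB, active) {
    idx <- which(active)
    if (!length(idx)) return(list(Y = Y, G = G, XB = XB))
    Ya <- Y[idx, , drop = FALSE]
    Ga <- G[idx, , , drop = FALSE]
    XBa <- XB[idx, , drop = FALSE]
    stage <- function(Yc, Gc) {
      bi <- batch_ingredients(model, partition, Yc, XBa)
      XBa <<- bi$XB
      dG <- array(0, dim(Gc))
      for (k in seq_along(idx)) {
        dG[k, , ] <- matrix(bi$Lambda[k, , ], nb, nb) %*%
          matrix(Gc[k, , ], nb, nb)
      }
      list(dY = bi$v, dG = dG)
    }
    k1 <- stage(Ya, Ga)
    k2 <- stage(Ya + h / 2 * k1$dY, Ga + h / 2 * k1$dG)
    k3 <- stage(Ya + h / 2 * k2$dY, Ga + h / 2 * k2$dG)
    k4 <- stage(Ya + h * k3$dY, Ga + h * k3$dG)
    Y[idx, ] <- Ya + h / 6 * (k1$dY + 2 * k2$dY + 2 * k3$dY + k4$dY)
    G[idx, , ] <- Ga + h / 6 * (k1$dG + 2 * k2$dG + 2 * k3$dG + k4$dG)
    XB[idx, ] <- XBa
    list(Y = Y, G = G, XB = XB)
  }

  cacheo <- new.env()
  M_now <- node_memory(Y, G, Cm, XB, active)
  PHI[1, ] <- ing0$v   # memory integral is empty at t = 0

  for (k in seq_len(nsteps)) {
    phi_k <- qss_drift(model, partition, XS[k, ], cache = cacheo) +
      trapz_memory(M_now)
    if (k == 1L) PHI[1, ] <- phi_k

    adv <- advance_aux(Y, G, XB, active)
    Y <- adv$Y; G <- adv$G; XB <- adv$XB
    gn <- apply(abs(matrix(G, nrow(Y), nb * nb)), 1, max)
    active <- active & (gn > trunc_tol)

    # predictor, then two corrector sweeps on the new node
    xs_new <- XS[k, ] + h * phi_k
    for (it in 1:2) {
      ing_new <- memory_ingredients(model, partition, xs_new, cache = cacheo)
      Yt <- rbind(Y, xs_new)
      Gt <- array(0, c(nrow(Y) + 1L, nb, nb))
      Gt[seq_len(nrow(Y)), , ] <- G
      Gt[nrow(Y) + 1L, , ] <- diag(nb)
      Cmt <- rbind(Cm, ing_new$c)
      XBt <- rbind(XB, ing_new$xb)
      activet <- c(active, TRUE)
      M_new <- node_memory(Yt, Gt, Cmt, XBt, activet)
      phi_new <- ing_new$v + trapz_memory(M_new)
      xs_new <- XS[k, ] + h / 2 * (phi_k + phi_new)
    }
    XS[k + 1L, ] <- xs_new
    PHI[k + 1L, ] <- phi_new
    Y <- Yt; G <- Gt; Cm <- Cmt; XB <- XBt; active <- activet
    ing_fin <- memory_ingredients(model, partition, xs_new, cache = cacheo)
    Y[nrow(Y), ] <- xs_new
    Cm[nrow(Cm), ] <- ing_fin$c
    XB[nrow(XB), ] <- ing_fin$xb
    M_now <- M_new
    M_now[nrow(M_now), ] <- drop(ing_fin$B %*% ing_fin$c)
  }

  new_trajectory(times, XS, PHI, species = partition$sub_names,
                 variant = "zmn", model = model, partition = partition)
}

#' Write a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV holds `time` plus one column per species; the sidecar (same path
#' with extension `.json`) records the variant, species, time range and a
#' hash of the generating model so that exported runs remain traceable.
#'
#' @param traj a `memnet_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "memnet_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  model <- attr(traj, "model")
  meta <- list(
    variant = attr(traj, "variant"),
    species = attr(traj, "species"),
    t_end = max(traj$time),
    n_nodes = nrow(traj),
    model_hash = if (!is.null(model)) {
      rlang::hash(list(model$species, model$rates, model$params))
    }
  )
  jsonlite::write_json(meta, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.memnet_trajectory <- function(x, ...) {
  cat("<memnet_trajectory> variant: ", attr(x, "variant"),
      ", t in [0, ", format(max(x$time), digits = 6), "], ",
      nrow(x), " nodes\n", sep = "")
  NextMethod()
}
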