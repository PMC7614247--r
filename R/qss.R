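#' Bulk quasi-steady-state solver
#'
#' Solves `R^b(x^s, x^b) = 0` for the bulk state at a prescribed subnetwork
#' state, by damped Newton iteration with the analytic bulk Jacobian. Without
#' a `guess`, a deterministic multi-start (origin, cached previous solution,
#' and 8 Halton points in a bulk box inferred from production/degradation
#' balance) is used; if the starts converge to distinct roots separated by
#' more than `1e-6`, the method's unique-QSS precondition is violated and an
#' error is raised.
#'
#' @param model a `memnet_model` (or a [qss_map()] object, in which case
#'   `partition` is taken from it).
#' @param partition a `memnet_partition`.
#' @param xs subnetwork state vector.
#' @param guess optional bulk start vector (skips multi-start).
#' @param tol residual tolerance (max-norm), default `1e-12`.
#' @param max_iter Newton iteration cap.
#' @param cache optional environment; field `last` is used as a warm start and
#'   updated, giving continuation behaviour along continuous `xs` paths.
#' @return the bulk state `x^b*`, with the bulk Jacobian's condition number in
#'   attribute `"condition_number"`.
#' @export
solve_qss <- function(model, partition = NULL, xs, guess = NULL,
                      tol = 1e-12, max_iter = 50L, cache = NULL) {
  if (inherits(model, "memnet_qss_map")) {
    qm <- model
    model <- qm$model; partition <- qm$partition
    tol <- qm$tol; max_iter <- qm$max_iter; cache <- qm$cache
  }
  stopifnot(inherits(model, "memnet_model"),
            inherits(partition, "memnet_partition"))
  nb <- length(partition$bulk)
  if (nb == 0L) return(numeric(0))
  if (any(!is.finite(xs))) stop("non-finite subnetwork state")

  if (!is.null(guess)) {
    res <- qss_newton(model, partition, xs, guess, tol, max_iter)
    if (!res$converged) {
      stop("QSS Newton did not converge (residual ",
           format(res$residual, digits = 3), ")")
    }
    if (!is.null(cache)) cache$last <- res$xb
    return(res$xb)
  }

  # warm-start fast path: during continuation (integration, grid sweeps) the
  # cached previous solution is an excellent start; the full multi-start
  # uniqueness sweep runs only on cold calls
  if (!is.null(cache) && !is.null(cache$last)) {
    res <- qss_newton(model, partition, xs, cache$last, tol, max_iter)
    if (res$converged) {
      cache$last <- res$xb
      return(res$xb)
    }
  }

  starts <- list(rep(0, nb))
  if (!is.null(cache) && !is.null(cache$last)) {
    starts <- c(list(cache$last), starts)
  }
  upper <- bulk_scale_box(model, partition)
  hp <- halton_points(8L, nb)
  for (k in seq_len(nrow(hp))) starts <- c(starts, list(hp[k, ] * upper))

  roots <- list()
  best_res <- Inf
  for (st in starts) {
    res <- qss_newton(model, partition, xs, st, tol, max_iter)
    if (res$converged) {
      roots <- c(roots, list(res$xb))
    } else {
      best_res <- min(best_res, res$residual)
    }
  }
  if (!length(roots)) {
    stop("QSS solve failed from all starts (best residual ",
         format(best_res, digits = 3), ")")
  }
  merged <- roots[1]
  for (r in roots[-1]) {
    if (all(vapply(merged, function(m) max(abs(m - r)) > 1e-6, logical(1)))) {
      merged <- c(merged, list(r))
    }
  }
  if (length(merged) > 1L) {
    stop("bulk QSS is not unique at this subnetwork state: found ",
         length(merged), " distinct roots; the unique-QSS assumption of the ",
         "reduction is violated")
  }
  out <- merged[[1]]
  if (!is.null(cache)) cache$last <- out
  out
}

qss_newton <- function(model, partition, xs, xb0, tol, max_iter) {
  sub <- partition$sub; bulk <- partition$bulk
  nb <- length(bulk)
  x <- numeric(length(model$species))
  x[sub] <- xs
  xb <- xb0
  # only the bulk rate expressions and the bulk-bulk derivative block are
  # needed inside the Newton loop; evaluating just those keeps this hot path
  # cheap inside integrator right-hand sides
  bulk_exprs <- model$expr[bulk]
  dBB <- if (!is.null(model$dexpr)) model$dexpr[bulk, bulk, drop = FALSE]
  eval_rb <- function() {
    # arithmetic on invalid states yields NaN/Inf rather than errors (no
    # conditionals or foreign functions in the expression language), so a
    # finiteness check downstream suffices
    ev <- state_env(model, x)
    vapply(bulk_exprs, eval, numeric(1), envir = ev)
  }
  eval_J <- function() {
    if (is.null(dBB)) {
      return(jacobian_full(model, x)[bulk, bulk, drop = FALSE])
    }
    ev <- state_env(model, x)
    matrix(vapply(dBB, eval, numeric(1), envir = ev), nb, nb)
  }
  for (it in seq_len(max_iter)) {
    x[bulk] <- xb
    rb <- eval_rb()
    if (is.null(rb) || any(!is.finite(rb))) {
      return(list(converged = FALSE, residual = Inf, xb = xb))
    }
    rn <- max(abs(rb))
    if (rn <= tol) {
      xbfinal <- xb
      attr(xbfinal, "condition_number") <- kappa(eval_J(), exact = FALSE)
      return(list(converged = TRUE, residual = rn, xb = xbfinal))
    }
    J <- eval_J()
    step <- tryCatch(-solve(J, rb), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(converged = FALSE, residual = rn, xb = xb))
    }
    # damping: halve the step until the residual norm decreases
    lam <- 1
    for (h in 1:30) {
      x[bulk] <- xb + lam * step
      rt <- eval_rb()
      if (!is.null(rt) && all(is.finite(rt)) && max(abs(rt)) < rn) break
      lam <- lam / 2
    }
    xb <- xb + lam * step
  }
  x[bulk] <- xb
  rb <- eval_rb()
  rn <- if (is.null(rb)) Inf else max(abs(rb))
  list(converged = rn <= tol, residual = rn, xb = xb)
}

# rough per-bulk-species scale: production at the origin over linear
# degradation there, floored; deterministic
bulk_scale_box <- function(model, partition) {
  x0 <- rep(0, length(model$species))
  r0 <- tryCatch(evaluate_rates(model, x0), error = function(e) NULL)
  J0 <- tryCatch(jacobian_full(model, x0), error = function(e) NULL)
  vapply(seq_along(partition$bulk), function(k) {
    i <- partition$bulk[k]
    prod <- if (is.null(r0)) 1 else max(abs(r0[i]), 1)
    degr <- if (is.null(J0)) 1 else max(-J0[i, i], 0.1)
    max(1, 3 * prod / degr)
  }, numeric(1))
}

# deterministic low-discrepancy points in [0,1]^dim (van der Corput / Halton)
halton_points <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (dim > length(primes)) stop("halton_points: dimension too large")
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    for (i in seq_len(n)) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, d] <- r
    }
  }
  out
}

#' QSS solver handle with continuation cache
#'
#' Bundles a model, a partition and solver options together with a cache
#' environment, so that repeated [solve_qss()]/[qss_drift()] calls along a
#' continuous subnetwork path warm-start from the previous bulk solution.
#'
#' @inheritParams solve_qss
#' @param n_starts number of Halton multi-start points (cold starts).
#' @export
qss_map <- function(model, partition, tol = 1e-12, max_iter = 50L,
                    n_starts = 8L) {
  stopifnot(inherits(model, "memnet_model"),
            inherits(partition, "memnet_partition"))
  structure(
    list(model = model, partition = partition, tol = tol,
         max_iter = max_iter, n_starts = n_starts, cache = new.env()),
    class = "memnet_qss_map"
  )
}

#' QSS drift of the reduced subnetwork
#'
#' Evaluates `v(x^s) = R^s(x^s, x^b*(x^s))`, the memoryless (fast-bulk)
#' approximation to the subnetwork dynamics. With an empty bulk this is just
#' `R^s`.
#'
#' @inheritParams solve_qss
#' @return named numeric drift vector over the subnetwork species.
#' @export
qss_drift <- function(model, partition = NULL, xs, guess = NULL,
                      cache = NULL, tol = 1e-12) {
  if (inherits(model, "memnet_qss_map")) {
    qm <- model; model <- qm$model
    partition <- partition %||% qm$partition
    cache <- cache %||% qm$cache
    tol <- qm$tol
  }
  xb <- solve_qss(model, partition, xs, guess = guess, cache = cache,
                  tol = tol)
  x <- numeric(length(model$species))
  x[partition$sub] <- xs
  x[partition$bulk] <- xb
  evaluate_rates(model, x)[partition$sub]
}

# Jacobian of the QSS drift: V = S - B J^{-1} A (all blocks at QSS)
qss_drift_jacobian <- function(model, partition, xs, cache = NULL) {
  sub <- partition$sub; bulk <- partition$bulk
  xb <- solve_qss(model, partition, xs, cache = cache)
  x <- numeric(length(model$species))
  x[sub] <- xs; x[bulk] <- xb
  Jf <- jacobian_full(model, x)
  S <- Jf[sub, sub, drop = FALSE]
  if (!length(bulk)) return(S)
  B <- Jf[sub, bulk, drop = FALSE]
  A <- Jf[bulk, sub, drop = FALSE]
  J <- Jf[bulk, bulk, drop = FALSE]
  S - B %*% solve(J, A)
}

#' Integrate the QSS-reduced flow
#'
#' Solves `d x^s/d tau = v(x^s)` from `xs0` on the given time grid with an
#' adaptive stiff-capable method (`deSolve::lsoda`) and returns a trajectory
#' with dense (cubic Hermite) interpolation.
#'
#' @inheritParams solve_qss
#' @param xs0 initial subnetwork state.
#' @param times increasing time grid starting at 0, or a single end time
#'   (expanded to 201 grid points).
#' @param rtol,atol integrator tolerances.
#' @return a `memnet_trajectory` tibble (columns `time` and the subnetwork
#'   species).
#' @export
qss_flow <- function(model, partition, xs0, times, rtol = 1e-9, atol = 1e-12) {
  times <- expand_times(times)
  cache <- new.env()
  rhs <- function(t, y, p) {
    list(unname(qss_drift(model, partition, y, cache = cache)))
  }
  sol <- run_desolve(rhs, xs0, times, rtol, atol)
  new_trajectory(sol$times, sol$states, sol$derivs,
                 species = partition$sub_names, variant = "qss",
                 model = model, partition = partition)
}

expand_times <- function(times) {
  if (length(times) == 1L) times <- seq(0, times, length.out = 201L)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must start at 0 and be strictly increasing")
  }
  times
}

# batch QSS solve: one Newton iteration loop over all rows simultaneously,
# warm-started from `guesses` (rows). Used by the ZMn history auxiliaries.
solve_qss_batch <- function(model, partition, xs_mat, guesses,
                            tol = 1e-12, max_iter = 50L) {
  sub <- partition$sub; bulk <- partition$bulk
  nb <- length(bulk)
  nr <- nrow(xs_mat)
  if (nb == 0L) return(matrix(0, nr, 0))
  n <- length(model$species)
  X <- matrix(0, nr, n)
  X[, sub] <- xs_mat
  XB <- guesses
  active <- rep(TRUE, nr)
  for (it in seq_len(max_iter)) {
    X[, bulk] <- XB
    R <- evaluate_rates(model, X)[, bulk, drop = FALSE]
    rn <- apply(abs(R), 1, max)
    active <- rn > tol
    if (!any(active)) break
    idx <- which(active)
    Jarr <- jacobian_batch(model, X[idx, , drop = FALSE])
    if (nb == 1L) {
      XB[idx, 1] <- XB[idx, 1] - R[idx, 1] / Jarr[, bulk, bulk]
    } else {
      for (k in seq_along(idx)) {
        J <- matrix(Jarr[k, bulk, bulk], nb, nb)
        XB[idx[k], ] <- XB[idx[k], ] - solve(J, R[idx[k], ])
      }
    }
  }
  if (any(active)) {
    # fall back to the robust scalar solver for stragglers
    for (i in which(active)) {
      XB[i, ] <- solve_qss(model, partition, xs_mat[i, ], guess = guesses[i, ],
                           tol = tol)
    }
  }
  XB
}
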