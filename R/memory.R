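#' Time-ordered propagator of bulk deviations along the QSS flow
#'
#' Computes the matrix `G(tau)` solving `dG/dtau = Lambda(phi_v(x^s, tau)) G`
#' with `G(0) = I`, where `Lambda = J + J^{-1} A B` is the bulk-deviation
#' relaxation generator and `phi_v` the QSS flow started at `x^s`. `G` is the
#' time-ordered exponential of `Lambda` along the flow (in index notation it
#' is the transpose of the propagator built from the l-matrix); the
#' orientation used here is certified by the scalar-case quadrature oracle,
#' the linear-bulk exactness of the self-consistent reduction and the
#' linearized-kernel impulse response. For a single bulk species it reduces to
#' `exp(int_0^tau Lambda dtau')`; at a fixed point of the QSS drift it is the
#' ordinary matrix exponential `expm(tau Lambda)`.
#'
#' @inheritParams solve_qss
#' @param tau non-negative evaluation time(s).
#' @param rtol,atol integrator tolerances for the joint flow/propagator ODE.
#' @return for scalar `tau`, the (bulk x bulk) matrix `G(tau)`; for a vector,
#'   a list with `tau`, `G` (array `length(tau) x nb x nb`) and `flow` (matrix
#'   of transported subnetwork states `phi_v(x^s, tau)` in rows).
#' @export
propagator <- function(model, partition, xs, tau, rtol = 1e-10, atol = 1e-12) {
  scalar <- length(tau) == 1L
  out <- propagate_flow(model, partition, xs, tau, rtol = rtol, atol = atol)
  if (scalar) {
    return(matrix(out$G[1, , ], length(partition$bulk), length(partition$bulk)))
  }
  out
}

# joint ODE for y = phi_v(x^s, tau) and G(tau); taus need not include 0
propagate_flow <- function(model, partition, xs, taus, rtol = 1e-10,
                           atol = 1e-12) {
  stopifnot(all(taus >= 0), !is.unsorted(taus))
  ns <- length(partition$sub); nb <- length(partition$bulk)
  if (max(taus) == 0) {
    G <- array(0, dim = c(length(taus), nb, nb))
    for (i in seq_len(nb)) G[, i, i] <- 1
    return(list(tau = taus,
                flow = matrix(xs, length(taus), ns, byrow = TRUE),
                G = G))
  }
  cache <- new.env()
  rhs <- function(t, y, p) {
    xsv <- y[seq_len(ns)]
    ing <- memory_ingredients(model, partition, xsv, cache = cache)
    if (nb == 0L) return(list(ing$v))
    G <- matrix(y[-seq_len(ns)], nb, nb)
    list(c(unname(ing$v), as.vector(ing$Lambda %*% G)))
  }
  y0 <- c(xs, as.vector(diag(nb)))
  tgrid <- if (taus[1] > 0) c(0, taus) else taus
  sol <- deSolve::ode(y = y0, times = tgrid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  check_desolve(sol, tgrid)
  keep <- match(taus, tgrid)
  states <- unname(as.matrix(sol[keep, -1, drop = FALSE]))
  list(tau = taus,
       flow = states[, seq_len(ns), drop = FALSE],
       G = array(states[, -seq_len(ns), drop = FALSE],
                 dim = c(length(taus), nb, nb)))
}

#' Nonlinear memory function M(x^s, tau)
#'
#' The memory correction to the QSS drift: `M(x^s, tau)` gives, per
#' subnetwork species, the rate contribution at delay `tau` from the
#' subnetwork having been at state `x^s` a time `tau` ago. It is computed from
#' the closed form `M(x^s, tau) = B(phi_v(x^s, tau)) G(tau) c(x^s)`: the
#' prefactor `c` measures how fast the bulk is being pushed away from QSS at
#' `x^s`, the propagator `G` transports that deviation along the QSS flow,
#' and the coupling `B` (the `f0` derivatives at the transported point) feeds
#' it back into the subnetwork. `M` vanishes identically at every fixed point
#' of the QSS drift.
#'
#' @inheritParams propagator
#' @param tau vector of non-negative delays.
#' @return a tibble with column `tau` and one memory column per subnetwork
#'   species; the evaluation state is in attribute `"xs"`, the transported
#'   flow points in attribute `"flow"`.
#' @export
memory_function <- function(model, partition, xs, tau, rtol = 1e-10,
                            atol = 1e-12) {
  ns <- length(partition$sub); nb <- length(partition$bulk)
  tau <- sort(unique(tau))
  ing <- memory_ingredients(model, partition, xs)
  if (nb == 0L) {
    out <- tibble::as_tibble(matrix(0, length(tau), ns,
                                    dimnames = list(NULL, partition$sub_names)))
    out <- dplyr::bind_cols(tibble::tibble(tau = tau), out)
    attr(out, "xs") <- xs
    return(out)
  }
  pf <- propagate_flow(model, partition, xs, tau, rtol = rtol, atol = atol)
  M <- matrix(0, length(tau), ns)
  cache <- new.env()
  for (k in seq_along(tau)) {
    ik <- memory_ingredients(model, partition, pf$flow[k, ], cache = cache)
    G <- matrix(pf$G[k, , ], nb, nb)
    M[k, ] <- ik$B %*% (G %*% ing$c)
  }
  colnames(M) <- partition$sub_names
  out <- dplyr::bind_cols(tibble::tibble(tau = tau), tibble::as_tibble(M))
  attr(out, "xs") <- xs
  attr(out, "flow") <- pf$flow
  out
}

#' Instantaneous memory amplitude M(x^s, 0)
#'
#' Zero-delay memory strength, `B(x^s) c(x^s)`, without any flow propagation.
#'
#' @inheritParams solve_qss
#' @return named numeric vector over subnetwork species.
#' @export
memory_amplitude <- function(model, partition, xs, cache = NULL) {
  ing <- memory_ingredients(model, partition, xs, cache = cache)
  if (!length(partition$bulk)) {
    return(stats::setNames(numeric(length(partition$sub)),
                           partition$sub_names))
  }
  stats::setNames(drop(ing$B %*% ing$c), partition$sub_names)
}

#' Linearized memory kernel at a fixed point
#'
#' Near a fixed point `x^s*` of the QSS drift the (nonlinear and
#' self-consistent) memory terms reduce to one and the same time convolution
#' `int_0^t K(t - t') (x^s(t') - x^s*) dt'` with kernel
#' `K(tau) = B* exp(tau Lambda*) (J*^{-1} A*) V*`, obtained by freezing every
#' factor of the memory at the fixed point and differentiating the drift
#' factor inside `c` (the only factor vanishing there). Together with the
#' drift Jacobian `V*`, this kernel reproduces exactly the subnetwork block
#' of the full system linearized at the fixed point.
#'
#' @inheritParams solve_qss
#' @param fixed_point subnetwork coordinates of a fixed point of the QSS
#'   drift (drift residual must be below `residual_tol`).
#' @param residual_tol precondition tolerance on the drift residual.
#' @return an object of class `memnet_linear_kernel`: call it via
#'   [kernel_matrix()] or use [impulse_response()].
#' @export
linearized_kernel <- function(model, partition, fixed_point,
                              residual_tol = 1e-8) {
  ing <- memory_ingredients(model, partition, fixed_point)
  if (max(abs(ing$v)) > residual_tol) {
    stop("'fixed_point' is not a fixed point of the QSS drift (residual ",
         format(max(abs(ing$v)), digits = 3), ")")
  }
  structure(
    list(xs = fixed_point, B = ing$B, Lambda = ing$Lambda,
         JinvA = if (length(partition$bulk)) solve(ing$J, ing$A) else ing$A,
         V = ing$V, partition = partition),
    class = "memnet_linear_kernel"
  )
}

#' Evaluate a linearized memory kernel
#'
#' @param kernel a `memnet_linear_kernel`.
#' @param tau non-negative delay (scalar).
#' @return the (subnetwork x subnetwork) kernel matrix `K(tau)`.
#' @export
kernel_matrix <- function(kernel, tau) {
  stopifnot(inherits(kernel, "memnet_linear_kernel"))
  if (!nrow(kernel$Lambda)) {
    ns <- nrow(kernel$V)
    return(matrix(0, ns, ns))
  }
  E <- as.matrix(Matrix::expm(tau * kernel$Lambda))
  kernel$B %*% E %*% kernel$JinvA %*% kernel$V
}

#' @export
print.memnet_linear_kernel <- function(x, ...) {
  cat("<memnet_linear_kernel> at x^s* = (",
      paste(signif(x$xs, 6), collapse = ", "), ")\n", sep = "")
  if (nrow(x$Lambda)) {
    ev <- eigen(x$Lambda, only.values = TRUE)$values
    cat("  Lambda* eigenvalues: ",
        paste(format(ev, digits = 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Impulse response of the linearized projected system
#'
#' Integrates `d xi/dt = V* xi + int_0^t K(t - t') xi(t') dt'` from `xi(0)`,
#' rewriting the convolution exactly as the auxiliary ODE
#' `d mu/dt = Lambda* mu + (J*^{-1} A*) V* xi`, `mu(0) = 0` (valid because
#' `Lambda*` is constant). This is the reduced-system side of the exactness
#' property of the linearized kernel.
#'
#' @param kernel a `memnet_linear_kernel`.
#' @param xi0 initial subnetwork deviation from the fixed point.
#' @param times output time grid (starting at 0) or a single end time.
#' @param rtol,atol integrator tolerances.
#' @return tibble with `time` and one deviation column per subnetwork species.
#' @export
impulse_response <- function(kernel, xi0, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(kernel, "memnet_linear_kernel"))
  times <- expand_times(times)
  ns <- nrow(kernel$V); nb <- nrow(kernel$Lambda)
  CK <- if (nb) kernel$JinvA %*% kernel$V else NULL
  rhs <- function(t, y, p) {
    xi <- y[seq_len(ns)]
    if (!nb) return(list(drop(kernel$V %*% xi)))
    mu <- y[-seq_len(ns)]
    dxi <- kernel$V %*% xi + kernel$B %*% mu
    dmu <- kernel$Lambda %*% mu + CK %*% xi
    list(c(drop(dxi), drop(dmu)))
  }
  sol <- deSolve::ode(y = c(xi0, rep(0, nb)), times = times, func = rhs,
                      parms = NULL, rtol = rtol, atol = atol)
  check_desolve(sol, times)
  out <- tibble::as_tibble(as.data.frame(sol[, seq_len(ns + 1), drop = FALSE]))
  names(out) <- c("time", kernel$partition$sub_names)
  out
}

#' Closed-form random-force approximation
#'
#' Approximates the projected equation's random force for a bulk starting
#' away from QSS: `F^s(x^s, x^b, tau) = B(phi_v(x^s, tau)) G(tau)
#' (x^b - x^b*(x^s))`, linear in the initial bulk deviation. It vanishes for
#' all `tau` when the bulk starts at QSS, and at `tau = 0` it reduces to the
#' linearization of `R^s(x^s, x^b) - R^s(x^s, x^b*)` in the bulk deviation.
#'
#' @inheritParams propagator
#' @param xb bulk state (same length as the bulk).
#' @return a tibble with `tau` and one force column per subnetwork species.
#' @export
random_force <- function(model, partition, xs, xb, tau, rtol = 1e-10,
                         atol = 1e-12) {
  ns <- length(partition$sub); nb <- length(partition$bulk)
  tau <- sort(unique(tau))
  stopifnot(length(xb) == nb)
  if (nb == 0L) {
    out <- tibble::as_tibble(matrix(0, length(tau), ns,
                                    dimnames = list(NULL, partition$sub_names)))
    return(dplyr::bind_cols(tibble::tibble(tau = tau), out))
  }
  dev <- xb - solve_qss(model, partition, xs)
  pf <- propagate_flow(model, partition, xs, tau, rtol = rtol, atol = atol)
  Fm <- matrix(0, length(tau), ns)
  cache <- new.env()
  for (k in seq_along(tau)) {
    ik <- memory_ingredients(model, partition, pf$flow[k, ], cache = cache)
    G <- matrix(pf$G[k, , ], nb, nb)
    Fm[k, ] <- ik$B %*% (G %*% dev)
  }
  colnames(Fm) <- partition$sub_names
  dplyr::bind_cols(tibble::tibble(tau = tau), tibble::as_tibble(Fm))
}
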