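#' Locate and classify fixed points
#'
#' Multi-start damped-Newton root finding over a bounded box, with
#' deterministic low-discrepancy (Halton) starts, duplicate merging and
#' eigenvalue classification. Three system variants are supported:
#'
#' * `"full"` — roots of the full rate vector `R(x)`, classified by the full
#'   Jacobian;
#' * `"qss"` — roots of the QSS drift `v(x^s)`, classified by the drift
#'   Jacobian `V`;
#' * `"zms"` — the self-consistent reduced system. Its steady states coincide
#'   with those of the QSS drift (the memory prefactor `c` vanishes wherever
#'   `v` does, so the auxiliary memory settles at zero); stability is judged
#'   by the augmented Jacobian of `(x^s, m)`, which is similar to the full
#'   Jacobian.
#'
#' @param model a `memnet_model`.
#' @param box per-coordinate bounds: a length-2 vector `c(lo, hi)` applied to
#'   every coordinate, or a 2-row matrix with one column per coordinate
#'   (full dimension for `"full"`, subnetwork dimension otherwise).
#' @param partition a `memnet_partition` (required for `"qss"`/`"zms"`).
#' @param system which system's fixed points to find.
#' @param n_starts number of Halton starts (default 64).
#' @param merge_tol roots closer than this (max-norm) are merged.
#' @param residual_tol acceptance threshold on the rate residual.
#' @param marginal_tol eigenvalues with `|Re| <` this are flagged marginal
#'   rather than silently classified.
#' @return a tibble of class `memnet_fixed_points`: columns `system`, one
#'   coordinate column per species, `stability` (`stable`, `saddle`,
#'   `unstable`, or `marginal`), `lead_re`, `lead_im` (leading eigenvalue),
#'   `residual`, and a list column `eigenvalues`.
#' @export
find_fixed_points <- function(model, box, partition = NULL,
                              system = c("full", "qss", "zms"),
                              n_starts = 64L, merge_tol = 1e-6,
                              residual_tol = 1e-9, marginal_tol = 1e-8) {
  system <- match.arg(system)
  stopifnot(inherits(model, "memnet_model"))
  if (system != "full" && is.null(partition)) {
    stop("'partition' is required for system = '", system, "'")
  }
  coord_names <- if (system == "full") model$species else partition$sub_names
  d <- length(coord_names)
  if (is.matrix(box)) {
    stopifnot(nrow(box) == 2L, ncol(box) == d)
  } else {
    stopifnot(length(box) == 2L)
    box <- matrix(rep(box, d), nrow = 2L)
  }
  lo <- box[1, ]; hi <- box[2, ]

  fpcache <- new.env()
  resfun <- switch(system,
    full = function(x) unname(evaluate_rates(model, x)),
    function(x) unname(qss_drift(model, partition, x, cache = fpcache))
  )
  jacfun <- switch(system,
    full = function(x) jacobian_full(model, x),
    function(x) qss_drift_jacobian(model, partition, x, cache = fpcache)
  )

  starts <- sweep(halton_points(n_starts, d), 2, hi - lo, `*`)
  starts <- sweep(starts, 2, lo, `+`)
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    # polish to near machine precision; residual_tol is the acceptance
    # threshold, not the stopping tolerance (downstream properties such as
    # the vanishing of the memory at fixed points scale with the residual)
    r <- tryCatch(
      newton_solve(resfun, jacfun, starts[k, ],
                   tol = min(residual_tol / 10, 1e-13)),
      error = function(e) NULL
    )
    if (is.null(r)) next
    x <- r$x
    rres <- tryCatch(max(abs(resfun(x))), error = function(e) Inf)
    if (!is.finite(rres) || rres > residual_tol) next
    pad <- 0.05 * (hi - lo)
    if (any(x < lo - pad) || any(x > hi + pad)) next
    if (!length(roots) ||
        all(vapply(roots, function(m) max(abs(m - x)) > merge_tol,
                   logical(1)))) {
      roots <- c(roots, list(x))
    }
  }
  if (!length(roots)) {
    out <- tibble::as_tibble(matrix(numeric(0), 0, d,
                                    dimnames = list(NULL, coord_names)))
    out <- dplyr::bind_cols(tibble::tibble(system = character(0)), out,
                            tibble::tibble(stability = character(0),
                                           lead_re = numeric(0),
                                           lead_im = numeric(0),
                                           residual = numeric(0),
                                           eigenvalues = list()))
    class(out) <- c("memnet_fixed_points", class(out))
    return(out)
  }

  rows <- lapply(roots, function(x) {
    ev <- switch(system,
      full = eigen(jacobian_full(model, x), only.values = TRUE)$values,
      qss = eigen(jacfun(x), only.values = TRUE)$values,
      zms = eigen(zms_augmented_jacobian(model, partition, x),
                  only.values = TRUE)$values
    )
    ev <- ev[order(-Re(ev))]
    tibble::tibble(
      stability = classify_eigenvalues(ev, marginal_tol),
      lead_re = Re(ev[1]), lead_im = Im(ev[1]),
      residual = max(abs(resfun(x))),
      eigenvalues = list(ev)
    )
  })
  coords <- do.call(rbind, roots)
  colnames(coords) <- coord_names
  ord <- do.call(order, as.data.frame(coords))
  out <- dplyr::bind_cols(
    tibble::tibble(system = system),
    tibble::as_tibble(coords),
    dplyr::bind_rows(rows)
  )[ord, ]
  class(out) <- c("memnet_fixed_points", class(out))
  out
}

classify_eigenvalues <- function(ev, marginal_tol) {
  re <- Re(ev)
  if (any(abs(re) < marginal_tol)) return("marginal")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

# Jacobian of the augmented ZMs system d(x^s, m)/dt at a drift fixed point
# (m = 0 there): [[V, B], [J^{-1} A V, Lambda]]; similar to the full Jacobian
zms_augmented_jacobian <- function(model, partition, xs) {
  ing <- memory_ingredients(model, partition, xs)
  nb <- length(partition$bulk)
  if (!nb) return(ing$V)
  JiAV <- solve(ing$J, ing$A) %*% ing$V
  rbind(cbind(ing$V, ing$B), cbind(JiAV, ing$Lambda))
}

# generic damped Newton with analytic Jacobian
newton_solve <- function(f, jac, x0, tol = 1e-10, max_iter = 100L) {
  x <- x0
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    fn <- max(abs(fx))
    if (!is.finite(fn)) return(list(converged = FALSE, x = x))
    if (fn <= tol) return(list(converged = TRUE, x = x))
    J <- jac(x)
    step <- tryCatch(-solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      return(list(converged = FALSE, x = x))
    }
    lam <- 1
    repeat {
      xt <- x + lam * step
      ft <- tryCatch(f(xt), error = function(e) NULL)
      if (!is.null(ft) && all(is.finite(ft)) &&
          (max(abs(ft)) < fn || lam < 1e-8)) break
      lam <- lam / 2
    }
    if (lam < 1e-8 && max(abs(ft)) >= fn) {
      return(list(converged = max(abs(ft)) <= tol, x = xt))
    }
    x <- xt; fx <- ft
  }
  list(converged = max(abs(fx)) <= tol, x = x)
}

#' Extract stable fixed points as a coordinate matrix
#' @param fp a `memnet_fixed_points` tibble.
#' @return numeric matrix, one stable point per row.
#' @export
stable_points <- function(fp) {
  stopifnot(inherits(fp, "memnet_fixed_points"))
  coord_cols <- setdiff(names(fp), c("system", "stability", "lead_re",
                                     "lead_im", "residual", "eigenvalues"))
  as.matrix(fp[fp$stability == "stable", coord_cols, drop = FALSE])
}
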