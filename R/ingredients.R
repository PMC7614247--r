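#' Ingredients of the memory function at a subnetwork state
#'
#' Evaluates, at `(x^s, x^b*(x^s))`, every state-dependent object entering the
#' memory formulas:
#'
#' * `f0` — (bulk x subnetwork) matrix of derivatives `dR_s/dx_b` (stored with
#'   bulk as rows), the "incoming" coupling of bulk deviations into the
#'   subnetwork drift;
#' * `J` — bulk Jacobian `dR_b/dx_b'` (rows = bulk equations);
#' * `A` — `dR_b/dx_s'`, the "outgoing" coupling of the subnetwork into the
#'   bulk;
#' * `B` — `dR_s/dx_b` (subnetwork rows; `f0 = t(B)`);
#' * `Lambda = J + J^{-1} A B` — the relaxation generator of bulk deviations
#'   from QSS, in standard row-equation orientation (its transpose is the
#'   l-matrix in index notation `l_{bb'} = J_{b'b} + ...`);
#' * `c = J^{-1} A v` — the memory prefactor vector, where `v` is the QSS
#'   drift. `c` vanishes identically wherever `v = 0`, which is why the
#'   memory is zero at every fixed point of the reduced dynamics;
#' * `V = S - B J^{-1} A` — the Jacobian of the QSS drift.
#'
#' @inheritParams solve_qss
#' @return an object of class `memnet_ingredients` (a named list).
#' @export
memory_ingredients <- function(model, partition, xs, cache = NULL) {
  stopifnot(inherits(model, "memnet_model"),
            inherits(partition, "memnet_partition"))
  sub <- partition$sub; bulk <- partition$bulk
  ns <- length(sub); nb <- length(bulk)
  xb <- solve_qss(model, partition, xs, cache = cache)
  x <- numeric(length(model$species))
  x[sub] <- xs; x[bulk] <- xb
  R <- evaluate_rates(model, x)
  v <- R[sub]
  if (nb == 0L) {
    return(structure(
      list(xs = xs, xb = xb, x = x, v = v,
           f0 = matrix(0, 0, ns), B = matrix(0, ns, 0),
           A = matrix(0, 0, ns), J = matrix(0, 0, 0),
           Lambda = matrix(0, 0, 0), l = matrix(0, 0, 0),
           c = numeric(0),
           S = jacobian_full(model, x)[sub, sub, drop = FALSE],
           V = jacobian_full(model, x)[sub, sub, drop = FALSE]),
      class = "memnet_ingredients"))
  }
  Jf <- jacobian_full(model, x)
  S <- Jf[sub, sub, drop = FALSE]
  B <- Jf[sub, bulk, drop = FALSE]
  A <- Jf[bulk, sub, drop = FALSE]
  J <- Jf[bulk, bulk, drop = FALSE]
  Jinv_A <- tryCatch(solve(J, A), error = function(e) {
    stop("bulk Jacobian is singular at this subnetwork state (bulk block {",
         paste(partition$bulk_names, collapse = ", "), "})")
  })
  Lambda <- J + Jinv_A %*% B
  cvec <- drop(Jinv_A %*% v)
  V <- S - B %*% Jinv_A
  structure(
    list(xs = xs, xb = xb, x = x, v = v,
         f0 = t(B), B = B, A = A, J = J,
         Lambda = Lambda, l = t(Lambda), c = cvec,
         S = S, V = V),
    class = "memnet_ingredients"
  )
}

#' @export
print.memnet_ingredients <- function(x, ...) {
  cat("<memnet_ingredients> at x^s = (",
      paste(signif(x$xs, 6), collapse = ", "), ")\n", sep = "")
  cat("  |v| =", format(max(abs(x$v)), digits = 4),
      " |c| =", format(max(abs(x$c), 0), digits = 4), "\n")
  invisible(x)
}

# batch ingredients along rows of xs_mat; bulk warm-start matrix XB is
# required and updated in place semantics via return value
batch_ingredients <- function(model, partition, xs_mat, XB) {
  sub <- partition$sub; bulk <- partition$bulk
  ns <- length(sub); nb <- length(bulk)
  nr <- nrow(xs_mat)
  XB <- solve_qss_batch(model, partition, xs_mat, XB)
  n <- length(model$species)
  X <- matrix(0, nr, n)
  X[, sub] <- xs_mat
  if (nb) X[, bulk] <- XB
  R <- evaluate_rates(model, X)
  v <- R[, sub, drop = FALSE]
  Jarr <- jacobian_batch(model, X)
  Lambda <- array(0, c(nr, nb, nb))
  Barr <- array(0, c(nr, ns, nb))
  cmat <- matrix(0, nr, nb)
  if (nb == 1L) {
    # scalar-bulk fast path, fully vectorised over rows
    Jv <- Jarr[, bulk, bulk]
    Amat <- matrix(Jarr[, bulk, sub], nr, ns)
    Bmat <- matrix(Jarr[, sub, bulk], nr, ns)
    Lambda[, 1, 1] <- Jv + rowSums(Amat * Bmat) / Jv
    Barr[, , 1] <- Bmat
    cmat[, 1] <- rowSums(Amat * v) / Jv
    return(list(XB = XB, v = v, Lambda = Lambda, B = Barr, c = cmat))
  }
  for (k in seq_len(nr)) {
    Jf <- matrix(Jarr[k, , ], n, n)
    Bk <- Jf[sub, bulk, drop = FALSE]
    Ak <- Jf[bulk, sub, drop = FALSE]
    Jk <- Jf[bulk, bulk, drop = FALSE]
    JiA <- solve(Jk, Ak)
    Lambda[k, , ] <- Jk + JiA %*% Bk
    Barr[k, , ] <- Bk
    cmat[k, ] <- JiA %*% v[k, ]
  }
  list(XB = XB, v = v, Lambda = Lambda, B = Barr, c = cmat)
}
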