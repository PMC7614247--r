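#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixed-point table
#'
#' Drops the list column of eigenvalues, returning a plain tibble suitable
#' for CSV export (columns: system, coordinates, stability, leading
#' eigenvalue real/imaginary parts, residual).
#'
#' @param x a `memnet_fixed_points`.
#' @param ... unused.
#' @export
tidy.memnet_fixed_points <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$eigenvalues <- NULL
  out
}

#' One-row summary of a fixed-point table
#'
#' @param x a `memnet_fixed_points`.
#' @param ... unused.
#' @export
glance.memnet_fixed_points <- function(x, ...) {
  tibble::tibble(
    n_fixed_points = nrow(x),
    n_stable = sum(x$stability == "stable"),
    n_saddle = sum(x$stability == "saddle"),
    n_unstable = sum(x$stability == "unstable"),
    n_marginal = sum(x$stability == "marginal"),
    max_residual = if (nrow(x)) max(x$residual) else NA_real_
  )
}

#' Long-format view of a trajectory
#'
#' @param x a `memnet_trajectory`.
#' @param ... unused.
#' @export
tidy.memnet_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time", names_to = "species",
                      values_to = "concentration")
}

#' One-row summary of a basin map: per-variant resolution and agreement
#'
#' Agreement fractions are computed against the `"full"` variant when it is
#' present in the map.
#'
#' @param x a `memnet_basin_map`.
#' @param ... unused.
#' @export
glance.memnet_basin_map <- function(x, ...) {
  variants <- unique(x$variant)
  ref <- if ("full" %in% variants) "full" else variants[1]
  reflab <- x$label[x$variant == ref]
  dplyr::bind_rows(lapply(variants, function(v) {
    lab <- x$label[x$variant == v]
    tibble::tibble(
      variant = v,
      n_nodes = length(lab),
      frac_resolved = mean(!is.na(lab)),
      agreement_with_full = mean(lab == reflab, na.rm = TRUE)
    )
  }))
}
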