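#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory's time courses
#'
#' @param object a `memnet_trajectory`.
#' @param species optional subset of species columns to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.memnet_trajectory <- function(object, species = NULL, ...) {
  species <- species %||% attr(object, "species")
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration",
                  title = paste0("variant: ", attr(object, "variant"))) +
    ggplot2::theme_minimal()
}

#' Plot a basin-of-attraction map
#'
#' One facet per variant; tiles coloured by attractor label, unresolved
#' nodes blank, attractors overlaid as points.
#'
#' @param object a `memnet_basin_map` (2D subnetwork).
#' @param ... unused.
#' @export
autoplot.memnet_basin_map <- function(object, ...) {
  coords <- setdiff(names(object),
                    c("variant", "label", "t_converged", "resolved"))
  stopifnot(length(coords) == 2L)
  att <- tibble::as_tibble(as.data.frame(attr(object, "attractors")))
  names(att) <- coords
  ggplot2::ggplot(object,
                  ggplot2::aes(.data[[coords[1]]], .data[[coords[2]]],
                               fill = factor(.data$label))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = att, inherit.aes = FALSE,
                        ggplot2::aes(.data[[coords[1]]], .data[[coords[2]]]),
                        shape = 21, fill = "black", colour = "white",
                        size = 2) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(fill = "attractor") +
    ggplot2::theme_minimal()
}

#' Plot a memory-amplitude map with its zero contour
#'
#' @param object a `memnet_memory_map` over a 2D subnetwork.
#' @param species which subnetwork species' amplitude to show (default
#'   first).
#' @param ... unused.
#' @export
autoplot.memnet_memory_map <- function(object, species = NULL, ...) {
  coords <- names(object)[!startsWith(names(object), "M_")]
  stopifnot(length(coords) == 2L)
  species <- species %||% sub("^M_", "", setdiff(names(object), coords)[1])
  zcol <- paste0("M_", species)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data[[coords[1]]], .data[[coords[2]]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[zcol]])) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "orange") +
    ggplot2::labs(fill = paste0("M(", species, ", 0)")) +
    ggplot2::theme_minimal()
  ct <- attr(object, "contours")[[species]]
  if (!is.null(ct) && nrow(ct)) {
    p <- p + ggplot2::geom_path(data = ct,
                                ggplot2::aes(.data$x, .data$y,
                                             group = .data$piece),
                                colour = "black", linewidth = 0.8)
  }
  p
}

#' Plot a Hopf scan as a classified (a, n) grid
#'
#' @param object a `memnet_hopf_scan`.
#' @param ... unused.
#' @export
autoplot.memnet_hopf_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n, .data$a,
                                       fill = .data$verdict)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~variant) +
    ggplot2::theme_minimal()
}
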