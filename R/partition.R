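#' Partition a model into subnetwork and bulk species
#'
#' The subnetwork species `x^s` are tracked explicitly by the reduced
#' dynamics; the bulk species `x^b` are eliminated and replaced by their
#' quasi-steady state plus memory corrections. The two sets must be disjoint
#' and jointly cover all species; the subnetwork must be non-empty, while an
#' empty bulk is allowed as a degenerate case (the reduction is then the
#' identity and all memory terms vanish).
#'
#' @param model a `memnet_model`.
#' @param sub species names or indices forming the subnetwork.
#' @param bulk species names or indices forming the bulk; defaults to the
#'   complement of `sub`.
#' @return an object of class `memnet_partition` with integer index vectors
#'   `sub` and `bulk`.
#' @export
subnetwork_partition <- function(model, sub, bulk = NULL) {
  stopifnot(inherits(model, "memnet_model"))
  n <- length(model$species)
  sub <- resolve_species(model, sub, "sub")
  bulk <- if (is.null(bulk)) setdiff(seq_len(n), sub) else {
    resolve_species(model, bulk, "bulk")
  }
  if (length(sub) == 0L) stop("subnetwork must be non-empty")
  if (length(intersect(sub, bulk))) {
    stop("sub and bulk overlap: ",
         paste(model$species[intersect(sub, bulk)], collapse = ", "))
  }
  if (!setequal(c(sub, bulk), seq_len(n))) {
    stop("sub and bulk must jointly cover all species; missing: ",
         paste(model$species[setdiff(seq_len(n), c(sub, bulk))],
               collapse = ", "))
  }
  structure(
    list(sub = sub, bulk = bulk,
         sub_names = model$species[sub], bulk_names = model$species[bulk]),
    class = "memnet_partition"
  )
}

resolve_species <- function(model, x, what) {
  if (is.character(x)) {
    idx <- match(x, model$species)
    if (anyNA(idx)) {
      stop("unknown species in '", what, "': ",
           paste(x[is.na(idx)], collapse = ", "))
    }
    x <- idx
  }
  x <- as.integer(x)
  if (anyDuplicated(x) || any(x < 1L) || any(x > length(model$species))) {
    stop("invalid species indices in '", what, "'")
  }
  x
}

#' @export
print.memnet_partition <- function(x, ...) {
  cat("<memnet_partition> sub: {", paste(x$sub_names, collapse = ", "),
      "} | bulk: {", paste(x$bulk_names, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
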