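#' Read a network model from YAML or JSON config
#'
#' The config must contain keys `species` (list of names), `rates` (map
#' species -> expression string) and `params` (map name -> value), and may
#' contain `partition` with `sub` and `bulk` lists (retrievable afterwards
#' with [default_partition()]). JSON is detected by a leading `{` or `[`;
#' anything else is parsed as YAML.
#'
#' @param x config text (single string, possibly multi-line) or a file path.
#' @return a `memnet_model`.
#' @export
read_network_model <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    txt <- paste(x, collapse = "\n")
  }
  cfg <- if (grepl("^\\s*[{\\[]", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(txt)
  }
  if (is.null(cfg$species) || is.null(cfg$rates)) {
    stop("config must contain 'species' and 'rates'")
  }
  model <- network_model(
    species = unlist(cfg$species),
    rates = cfg$rates,
    params = cfg$params %||% list(),
    derivative_mode = cfg$derivative_mode %||% "symbolic"
  )
  if (!is.null(cfg$partition)) {
    attr(model, "default_partition") <-
      list(sub = unlist(cfg$partition$sub), bulk = unlist(cfg$partition$bulk))
  }
  model
}

#' Serialize a network model to config text
#'
#' Round-trips through [read_network_model()]: re-parsing the returned text
#' yields a model with identical rate evaluations.
#'
#' @param model a `memnet_model`.
#' @param partition optional `memnet_partition` to embed.
#' @param format `"yaml"` or `"json"`.
#' @param file optional path; if given the text is also written there.
#' @return config text, invisibly if `file` is given.
#' @export
write_network_model <- function(model, partition = NULL,
                                format = c("yaml", "json"), file = NULL) {
  stopifnot(inherits(model, "memnet_model"))
  format <- match.arg(format)
  cfg <- list(
    species = as.list(model$species),
    rates = as.list(model$rates),
    params = as.list(model$params),
    derivative_mode = model$derivative_mode
  )
  pt <- if (!is.null(partition)) {
    list(sub = as.list(model$species[partition$sub]),
         bulk = as.list(model$species[partition$bulk]))
  } else if (!is.null(attr(model, "default_partition"))) {
    dp <- attr(model, "default_partition")
    list(sub = as.list(dp$sub), bulk = as.list(dp$bulk))
  }
  if (!is.null(pt)) cfg$partition <- pt
  txt <- if (format == "yaml") {
    yaml::as.yaml(cfg)
  } else {
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
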