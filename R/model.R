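#' Define a dynamical network model
#'
#' A network model is a set of named species evolving as `dx/dt = R(x)`, with
#' one closed-form rate expression per species. Expressions may use the species
#' names, named parameters, the arithmetic operators `+ - * / ^` (with `**`
#' accepted as a synonym for `^`), parentheses, and the functions `exp`, `log`
#' and `sqrt`. Rate expressions must be smooth in the species; conditionals are
#' not allowed, since every downstream memory formula consumes first
#' derivatives of the rates.
#'
#' @param species character vector of species names (valid R symbols).
#' @param rates named character vector or list of rate expressions, one per
#'   species. Unnamed vectors are matched to `species` by position.
#' @param params named numeric vector/list of parameter values.
#' @param derivative_mode `"symbolic"` (default) differentiates the parsed
#'   expressions with [stats::D()]; `"fd"` uses central finite differences with
#'   step `max(1e-6, 1e-6 |x|)`. Finite differences are always available as a
#'   cross-check via [jacobian_full()].
#' @return an object of class `memnet_model`.
#' @seealso [fixture_model()], [build_model()], [evaluate_rates()],
#'   [jacobian_full()]
#' @examples
#' m <- network_model(
#'   species = c("x1", "x2"),
#'   rates = c(x1 = "a/(1 + x2^n) - x1", x2 = "a/(1 + x1^n) - x2"),
#'   params = c(a = 6, n = 3)
#' )
#' evaluate_rates(m, c(1, 1))
#' @export
network_model <- function(species, rates, params = list(),
                          derivative_mode = c("symbolic", "fd")) {
  derivative_mode <- match.arg(derivative_mode)
  species <- as.character(species)
  if (anyDuplicated(species)) {
    stop("duplicate species names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  bad <- species[make.names(species) != species]
  if (length(bad)) {
    stop("species names must be valid R symbols; offending: ",
         paste(bad, collapse = ", "))
  }
  rates <- as.list(rates)
  if (length(rates) != length(species)) {
    stop("need exactly one rate expression per species (",
         length(species), " species, ", length(rates), " rates)")
  }
  if (is.null(names(rates)) || all(names(rates) == "")) {
    names(rates) <- species
  }
  if (!setequal(names(rates), species)) {
    stop("rate names must match species names; missing: ",
         paste(setdiff(species, names(rates)), collapse = ", "))
  }
  rates <- rates[species]
  rates <- vapply(rates, as.character, character(1))

  params <- unlist(params)
  if (length(params) && (is.null(names(params)) || any(names(params) == ""))) {
    stop("params must be named")
  }
  params <- vapply(as.list(params), as.numeric, numeric(1))

  exprs <- lapply(rates, parse_rate_expression)
  for (sp in species) {
    validate_rate_symbols(exprs[[sp]], sp, species, names(params))
  }

  # parameters are substituted into the compiled expressions once, so rate and
  # derivative evaluation only ever looks up species values
  param_list <- lapply(params, identity)
  cexprs <- lapply(exprs, function(e) {
    eval(call("substitute", e, param_list))
  })

  model <- structure(
    list(
      species = species,
      rates = rates,
      params = params,
      derivative_mode = derivative_mode,
      expr = cexprs
    ),
    class = "memnet_model",
    eval_env = new.env(parent = baseenv())
  )

  if (derivative_mode == "symbolic") {
    model$dexpr <- tryCatch(
      symbolic_jacobian_exprs(cexprs, species),
      error = function(e) {
        warning("symbolic differentiation failed (", conditionMessage(e),
                "); falling back to finite differences")
        NULL
      }
    )
    if (is.null(model$dexpr)) model$derivative_mode <- "fd"
  }
  model
}

# parse a single rate expression string, accepting ** as a power synonym
parse_rate_expression <- function(text) {
  text <- gsub("**", "^", text, fixed = TRUE)
  out <- tryCatch(parse(text = text, keep.source = FALSE),
                  error = function(e) {
                    stop("unparsable rate expression: '", text, "' (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  if (length(out) != 1L) {
    stop("rate expression must be a single expression: '", text, "'",
         call. = FALSE)
  }
  out[[1]]
}

.allowed_funs <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt")

validate_rate_symbols <- function(e, rate_name, species, param_names) {
  syms <- all.vars(e)
  funs <- setdiff(all.names(e), syms)
  unknown <- setdiff(syms, c(species, param_names))
  if (length(unknown)) {
    stop("rate for '", rate_name, "' references undeclared symbol",
         if (length(unknown) > 1) "s" else "", " ",
         paste0("'", unknown, "'", collapse = ", "), call. = FALSE)
  }
  badf <- setdiff(funs, .allowed_funs)
  if (length(badf)) {
    stop("rate for '", rate_name, "' uses unsupported function",
         if (length(badf) > 1) "s" else "", " ",
         paste0("'", badf, "'", collapse = ", "),
         "; allowed: ", paste(.allowed_funs, collapse = " "), call. = FALSE)
  }
  invisible(TRUE)
}

symbolic_jacobian_exprs <- function(cexprs, species) {
  n <- length(species)
  out <- vector("list", n * n)
  dim(out) <- c(n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[[i, j]] <- stats::D(cexprs[[i]], species[j])
    }
  }
  out
}

# reusable per-model evaluation environment: species values are overwritten
# on every call, so evaluation allocates no new environments in hot loops
state_env <- function(model, state) {
  ev <- attr(model, "eval_env")
  if (is.null(ev)) ev <- new.env(parent = baseenv())
  for (j in seq_along(model$species)) {
    assign(model$species[j], state[[j]], envir = ev)
  }
  ev
}

# rows of `states` are states; returns an (nstate x nspecies) matrix
eval_exprs_batch <- function(model, exprs, states) {
  ev <- new.env(parent = baseenv())
  nr <- nrow(states)
  for (j in seq_along(model$species)) {
    assign(model$species[j], states[, j], envir = ev)
  }
  vapply(exprs, function(e) {
    v <- eval(e, ev)
    if (length(v) == 1L) v <- rep.int(v, nr)
    v
  }, numeric(nr))
}

#' Evaluate the rate vector R(x)
#'
#' @param model a `memnet_model`.
#' @param state numeric state vector (one entry per species), or a matrix with
#'   one state per row for vectorised evaluation.
#' @return numeric vector `R(state)` (or matrix, states in rows).
#' @export
evaluate_rates <- function(model, state) {
  stopifnot(inherits(model, "memnet_model"))
  if (is.matrix(state)) {
    stopifnot(ncol(state) == length(model$species))
    out <- matrix(eval_exprs_batch(model, model$expr, state),
                  nrow = nrow(state),
                  dimnames = list(NULL, model$species))
    if (anyNA(out) || any(!is.finite(out))) {
      bad <- model$species[unique(which(!is.finite(out), arr.ind = TRUE)[, 2])]
      stop("non-finite rate for species ", paste(bad, collapse = ", "))
    }
    return(out)
  }
  if (length(state) != length(model$species)) {
    stop("state must have one entry per species (expected ",
         length(model$species), ", got ", length(state), ")")
  }
  ev <- state_env(model, state)
  out <- vapply(model$expr, eval, numeric(1), envir = ev)
  if (any(!is.finite(out))) {
    stop("non-finite rate for species ",
         paste(model$species[!is.finite(out)], collapse = ", "))
  }
  names(out) <- model$species
  out
}

#' Jacobian of the rate vector
#'
#' Entry `(i, j)` is the partial derivative of rate `i` with respect to species
#' `j`, evaluated at `state`. The bulk-bulk block of this matrix is the bulk
#' Jacobian entering every memory formula.
#'
#' @inheritParams evaluate_rates
#' @param mode `"symbolic"`, `"fd"`, or `NULL` to use the model's
#'   `derivative_mode`.
#' @return a square numeric matrix with species dimnames.
#' @export
jacobian_full <- function(model, state, mode = NULL) {
  stopifnot(inherits(model, "memnet_model"))
  mode <- mode %||% model$derivative_mode
  n <- length(model$species)
  if (mode == "symbolic" && !is.null(model$dexpr)) {
    ev <- state_env(model, state)
    out <- matrix(0, n, n, dimnames = list(model$species, model$species))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        out[i, j] <- eval(model$dexpr[[i, j]], ev)
      }
    }
  } else {
    out <- fd_jacobian(function(x) evaluate_rates(model, x), state)
    dimnames(out) <- list(model$species, model$species)
  }
  if (any(!is.finite(out))) stop("non-finite derivative in Jacobian")
  out
}

# batch Jacobian: returns an (nstate x n x n) array
jacobian_batch <- function(model, states) {
  n <- length(model$species)
  nr <- nrow(states)
  if (!is.null(model$dexpr)) {
    vals <- eval_exprs_batch(model, model$dexpr, states)
    array(vals, dim = c(nr, n, n))
  } else {
    out <- array(0, dim = c(nr, n, n))
    for (k in seq_len(nr)) out[k, , ] <- jacobian_full(model, states[k, ])
    out
  }
}

# central finite differences, step max(1e-6, 1e-6 |x|)
fd_jacobian <- function(f, x) {
  n <- length(x)
  f0 <- f(x)
  out <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- max(1e-6, 1e-6 * abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    out[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  out
}

#' Update model parameters
#'
#' Returns a new model with the given parameter values replaced; rate
#' expressions are recompiled.
#'
#' @param model a `memnet_model`.
#' @param ... named parameter values, or a single named vector/list.
#' @export
update_params <- function(model, ...) {
  stopifnot(inherits(model, "memnet_model"))
  dots <- list(...)
  if (length(dots) == 1L &&
      (is.null(names(dots)) || identical(names(dots), "")) &&
      !is.null(names(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  newp <- model$params
  unknown <- setdiff(names(dots), names(newp))
  if (length(unknown)) {
    stop("unknown parameter", if (length(unknown) > 1) "s" else "", ": ",
         paste(unknown, collapse = ", "))
  }
  newp[names(dots)] <- unlist(dots)
  network_model(model$species, model$rates, newp,
                derivative_mode = model$derivative_mode)
}

#' @export
print.memnet_model <- function(x, ...) {
  cat("<memnet_model> ", length(x$species), " species, derivative mode: ",
      x$derivative_mode, "\n", sep = "")
  for (sp in x$species) {
    cat("  d", sp, "/dt = ", x$rates[[sp]], "\n", sep = "")
  }
  if (length(x$params)) {
    cat("  params: ",
        paste(names(x$params), signif(x$params, 6), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
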