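#' Built-in fixture models
#'
#' Constructs one of the package's reference networks:
#'
#' * `"bistable2"` — two mutually repressing species,
#'   `dx_j/dt = a/(1 + x_i^n) - x_j`. Defaults `a = 6, n = 3`, which place the
#'   stable states at (6, 0.028)/(0.028, 6) with a saddle at (1.46, 1.46).
#'   Default partition: `x1` subnetwork, `x2` bulk.
#' * `"multistable_or"` — `N` species with "or"-logic cross-repression,
#'   `dx_j/dt = a/(1 + sum_{i != j} x_i^n) - x_j`. Defaults `N = 3, a = 4,
#'   n = 2` (tetrastable). Default partition: last species in the bulk.
#' * `"repressilator"` — cyclic repression `dx_j/dt = a/(1 + x_{j-1}^n) - x_j`
#'   with `x_0 = x_3`. Defaults `a = 5, n = 3` (sustained oscillations).
#'   Default partition: `x3` in the bulk.
#' * `"neural_tube4"` — an illustrative four-transcription-factor
#'   cross-repression circuit (Nkx2.2, Olig2, Irx3, Pax6) patterned on the
#'   vertebrate neural tube, with a scalar signal parameter `p` in \[0, 1\]
#'   entering as an activating input to Nkx2.2 and Olig2. The parameter values
#'   are illustrative, not a published parametrization; analyses on this
#'   fixture are qualitative. Default partition: Nkx2.2, Olig2 subnetwork;
#'   Irx3, Pax6 bulk.
#' * `"linear_bulk_demo"` — one subnetwork species and two bulk species whose
#'   rates are (at most) linear in the bulk with an asymmetric Hurwitz bulk
#'   matrix. On this model the self-consistent (ZMs) reduction is exact.
#'
#' @param fixture fixture name.
#' @param ... parameter overrides (e.g. `a = 4`, `n = 2`), plus `N` for
#'   `"multistable_or"`.
#' @return a `memnet_model` carrying a default partition retrievable with
#'   [default_partition()].
#' @export
fixture_model <- function(fixture, ...) {
  overrides <- list(...)
  N <- overrides$N
  overrides$N <- NULL
  model <- switch(
    fixture,
    bistable2 = {
      m <- or_gate_model(2, a = 6, n = 3)
      attr(m, "default_partition") <- list(sub = "x1", bulk = "x2")
      m
    },
    multistable_or = {
      N <- N %||% 3
      m <- or_gate_model(N, a = 4, n = 2)
      attr(m, "default_partition") <-
        list(sub = paste0("x", seq_len(N - 1)), bulk = paste0("x", N))
      m
    },
    repressilator = {
      m <- network_model(
        species = c("x1", "x2", "x3"),
        rates = c(x1 = "a/(1 + (x3*x3)^(n/2)) - x1",
                  x2 = "a/(1 + (x1*x1)^(n/2)) - x2",
                  x3 = "a/(1 + (x2*x2)^(n/2)) - x3"),
        params = c(a = 5, n = 3)
      )
      attr(m, "default_partition") <- list(sub = c("x1", "x2"), bulk = "x3")
      m
    },
    neural_tube4 = {
      m <- neural_tube_model()
      attr(m, "default_partition") <-
        list(sub = c("Nkx2.2", "Olig2"), bulk = c("Irx3", "Pax6"))
      m
    },
    linear_bulk_demo = {
      m <- network_model(
        species = c("x1", "y1", "y2"),
        rates = c(
          x1 = "1/(1 + x1^2) + b1*y1 + b2*y2 + b3*x1*y2 - d*x1",
          y1 = "2*x1^2/(1 + x1^2) - d1*y1 + k12*y2",
          y2 = "1/(1 + x1) + k21*y1 - d2*y2"
        ),
        params = c(b1 = 0.4, b2 = -0.25, b3 = 0.1, d = 0.6,
                   d1 = 1.0, k12 = 0.3, k21 = 0.2, d2 = 0.8)
      )
      attr(m, "default_partition") <- list(sub = "x1", bulk = c("y1", "y2"))
      m
    },
    stop("unknown fixture '", fixture, "'; available: bistable2, multistable_or, ",
         "repressilator, neural_tube4, linear_bulk_demo")
  )
  if (length(overrides)) {
    dp <- attr(model, "default_partition")
    model <- update_params(model, overrides)
    attr(model, "default_partition") <- dp
  }
  model
}

# Hill repression term |x|^n written as (x*x)^(n/2): identical to x^n on the
# positive orthant, but smooth and well defined for the transient negative
# excursions reduced (memory-corrected) trajectories can make, and for
# non-integer Hill exponents in parameter scans
hill_pow <- function(var, exponent = "n") {
  paste0("(", var, "*", var, ")^(", exponent, "/2)")
}

or_gate_model <- function(N, a, n) {
  species <- paste0("x", seq_len(N))
  rates <- vapply(seq_len(N), function(j) {
    others <- species[-j]
    paste0("a/(1 + ", paste0(hill_pow(others), collapse = " + "), ") - ",
           species[j])
  }, character(1))
  names(rates) <- species
  network_model(species, rates, params = c(a = a, n = n))
}

# Illustrative cross-repression circuit for the neural tube progenitor
# network: the signal p activates Nkx2.2 and Olig2; Irx3 and Pax6 form the
# bulk. Parameter values chosen for plausible multistability, not fitted.
neural_tube_model <- function() {
  network_model(
    species = c("Nkx2.2", "Olig2", "Irx3", "Pax6"),
    rates = c(
      "Nkx2.2" = paste0(
        "p*aN/((1 + ", hill_pow("(Olig2/kON)", "h"), ")*(1 + ",
        hill_pow("(Irx3/kIN)", "h"), ")*(1 + ",
        hill_pow("(Pax6/kPN)", "h"), ")) - Nkx2.2"),
      "Olig2" = paste0(
        "p*aO/((1 + ", hill_pow("(Nkx2.2/kNO)", "h"), ")*(1 + ",
        hill_pow("(Irx3/kIO)", "h"), ")) - Olig2"),
      "Irx3" = paste0(
        "aI/((1 + ", hill_pow("(Nkx2.2/kNI)", "h"), ")*(1 + ",
        hill_pow("(Olig2/kOI)", "h"), ")) - Irx3"),
      "Pax6" = paste0(
        "aP/((1 + ", hill_pow("(Nkx2.2/kNP)", "h"), ")*(1 + ",
        hill_pow("(Olig2/kOP)", "h"), ")) - Pax6")
    ),
    params = c(p = 0.65, h = 2,
               aN = 5, aO = 5, aI = 5, aP = 5,
               kON = 1, kIN = 1, kPN = 1,
               kNO = 1, kIO = 1,
               kNI = 1, kOI = 1,
               kNP = 1, kOP = 1)
  )
}

#' Default subnetwork/bulk partition of a fixture model
#'
#' @param model a `memnet_model` created by [fixture_model()] or
#'   [build_model()] from a config with a `partition` block.
#' @return a `memnet_partition`, or an error if the model carries none.
#' @export
default_partition <- function(model) {
  dp <- attr(model, "default_partition")
  if (is.null(dp)) stop("model carries no default partition")
  subnetwork_partition(model, sub = dp$sub, bulk = dp$bulk)
}

#' Build a model from a fixture name or a config
#'
#' Single entry point covering both built-in fixtures and user-supplied
#' configuration (YAML/JSON text or file). Fixture names are those of
#' [fixture_model()]; anything else is treated as config text or a file path
#' and parsed with [read_network_model()].
#'
#' @param spec fixture name, config text, or path to a YAML/JSON config file.
#' @param ... parameter overrides forwarded to [fixture_model()].
#' @return a `memnet_model`.
#' @export
build_model <- function(spec, ...) {
  fixtures <- c("bistable2", "multistable_or", "repressilator",
                "neural_tube4", "linear_bulk_demo")
  if (is.character(spec) && length(spec) == 1L && spec %in% fixtures) {
    return(fixture_model(spec, ...))
  }
  read_network_model(spec)
}
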