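#' Construct a kinetic model
#'
#' A `kinetic_model` bundles everything the rest of the package needs to
#' know about a dynamic system: the ODE right-hand side
#' \eqn{\dot x = f(x, u, \theta, t)}, an observation map \eqn{y = g(x)},
#' the ordered state and parameter names, and default parameter bounds.
#' Built-in models additionally carry hand-derived Jacobians (used by the
#' forward sensitivity equations) and a compiled right-hand side (used by
#' [simulate_model()] for speed).
#'
#' @param name Model identifier.
#' @param state_names Ordered character vector of state variables.
#' @param parameter_names Ordered character vector of kinetic parameters.
#' @param rhs Function `(state, inputs, params, time)` returning the state
#'   derivatives as a numeric vector of length `length(state_names)`.
#' @param observation Function `(state)` mapping a state vector to the
#'   observable vector. Defaults to the identity.
#' @param obs_names Names of the observables returned by `observation`.
#' @param default_bounds Named list of `c(lower, upper)` per parameter.
#' @param jac_state,jac_params Optional analytic Jacobians of `rhs` with
#'   respect to the states / the parameters, same signature as `rhs`,
#'   returning matrices (`n_state x n_state`, `n_state x n_param`). When
#'   absent, central finite differences of `rhs` are used.
#' @param obs_jac Optional Jacobian of `observation` with respect to the
#'   state (`n_obs x n_state` matrix as a function of state).
#' @param compiled Optional list `(func, initfunc, pack_parms)` describing
#'   a deSolve compiled-model entry point in the package shared library;
#'   `pack_parms(params, inputs)` must return the numeric `parms` vector
#'   the initializer expects.
#' @param units Optional named list of unit strings, carried as metadata
#'   only (no conversion is ever performed).
#'
#' @return An object of class `kinetic_model`.
#' @seealso [mm_model()], [phosphorolysis_model()], [get_model()]
#' @export
kinetic_model <- function(name, state_names, parameter_names, rhs,
                          observation = NULL, obs_names = state_names,
                          default_bounds = NULL,
                          jac_state = NULL, jac_params = NULL,
                          obs_jac = NULL, compiled = NULL, units = list()) {
  stopifnot(is.character(name), is.character(state_names),
            is.character(parameter_names), is.function(rhs))
  obs_identity <- is.null(observation)
  if (obs_identity) {
    observation <- function(state) state
    if (is.null(obs_jac)) {
      n <- length(state_names)
      obs_jac <- function(state) diag(1, n, n)
    }
  }
  structure(
    list(name = name,
         state_names = state_names,
         parameter_names = parameter_names,
         rhs = rhs,
         observation = observation,
         obs_names = obs_names,
         default_bounds = default_bounds,
         jac_state = jac_state,
         jac_params = jac_params,
         obs_jac = obs_jac,
         obs_identity = obs_identity,
         compiled = compiled,
         units = units),
    class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model>", x$name, "\n")
  cat("  states:     ", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters: ", paste(x$parameter_names, collapse = ", "), "\n")
  cat("  observables:", paste(x$obs_names, collapse = ", "), "\n")
  invisible(x)
}

#' Irreversible Michaelis-Menten rate equations
#'
#' Right-hand side of the substrate/product system
#' \deqn{dS/dt = -r_{max} S / (S + K_S), \qquad dP/dt = +r_{max} S / (S + K_S).}
#' Product formation exactly mirrors substrate consumption, so the total
#' mass S + P is conserved. When both `S` and `K_S` are zero the rate is
#' taken as its defined limit, 0.
#'
#' @param state Named or positional numeric vector `(S, P)` in g/L.
#' @param params Named numeric vector with `r_max` (maximum specific
#'   reaction rate, g/L/h) and `K_S` (half-saturation constant, g/L).
#' @return Numeric vector `(dS/dt, dP/dt)`.
#' @examples
#' mm_rhs(c(S = 1, P = 0), c(r_max = 2, K_S = 1))  # half-maximal rate
#' @export
mm_rhs <- function(state, params) {
  S <- state[[1]]
  r_max <- params[["r_max"]]
  K_S <- params[["K_S"]]
  denom <- S + K_S
  rate <- if (denom > 0) r_max * S / denom else 0
  c(-rate, rate)
}

#' The built-in Michaelis-Menten batch model
#'
#' Two states `S` (substrate) and `P` (product), both observed directly;
#' parameters `r_max` and `K_S`. Concentrations are carried in g/L and
#' time in hours.
#'
#' @return A [kinetic_model].
#' @export
mm_model <- function() {
  rhs <- function(state, inputs, params, time) mm_rhs(state, params)
  jac_state <- function(state, inputs, params, time) {
    S <- state[[1]]
    r_max <- params[["r_max"]]; K_S <- params[["K_S"]]
    denom <- S + K_S
    d <- if (denom > 0) r_max * K_S / denom^2 else 0
    matrix(c(-d, d, 0, 0), 2, 2,
           dimnames = list(c("S", "P"), c("S", "P")))
  }
  jac_params <- function(state, inputs, params, time) {
    S <- state[[1]]
    r_max <- params[["r_max"]]; K_S <- params[["K_S"]]
    denom <- S + K_S
    if (denom > 0) {
      d_rmax <- S / denom
      d_KS <- -r_max * S / denom^2
    } else {
      d_rmax <- 0; d_KS <- 0
    }
    matrix(c(-d_rmax, d_rmax, -d_KS, d_KS), 2, 2,
           dimnames = list(c("S", "P"), c("r_max", "K_S")))
  }
  kinetic_model(
    name = "michaelis_menten",
    state_names = c("S", "P"),
    parameter_names = c("r_max", "K_S"),
    rhs = rhs,
    default_bounds = list(r_max = c(0.1, 1000), K_S = c(0.01, 1000)),
    jac_state = jac_state,
    jac_params = jac_params,
    compiled = list(
      func = "mm_derivs", initfunc = "mm_init",
      pack_parms = function(params, inputs)
        c(params[["r_max"]], params[["K_S"]])),
    units = list(concentration = "g/L", time = "h"))
}

#' Gaussian-bell temperature scaling of a rate constant
#'
#' Scales a rate constant by
#' \eqn{\exp(-(T - T_{max})^2 / (2 T_{width})^2)}: the factor equals 1 at
#' the optimal temperature `T_max` and decays symmetrically on both
#' sides, with `T_width` setting the width of the bell. Note the
#' denominator is \eqn{(2 T_{width})^2 = 4 T_{width}^2}.
#'
#' @param k Base rate constant (at `T = T_max`).
#' @param temp Temperature in degrees C.
#' @param T_max Optimal temperature (degrees C).
#' @param T_width Width parameter (degrees C), strictly positive.
#' @return The temperature-adjusted rate, in `(0, k]`.
#' @export
temperature_factor <- function(k, temp, T_max, T_width) {
  stopifnot(T_width > 0)
  k * exp(-(temp - T_max)^2 / (2 * T_width)^2)
}

#' Net rate of reversible nucleoside phosphorolysis (QSSA form)
#'
#' Net rate of the reversible cleavage
#' `Thd + Pi <-> Thy + R1P` catalysed by a nucleoside phosphorylase,
#' reduced by the quasi-steady-state approximation on the
#' enzyme-substrate complex:
#' \deqn{v = Enz_0 \frac{k_1 k_2\, Thd\, Pi - k_{-1} k_{-2}\, Thy\, R1P}
#'                     {k_1 Thd\, Pi + k_{-2} Thy\, R1P + k_{-1} + k_2}.}
#' The elementary rates are reconstructed from the Michaelis form:
#' `k2 = k_catf`, `k-1 = k_catr`, `k1 = (k_catr + k_catf) / K_M_S`,
#' `k-2 = (k_catr + k_catf) / K_M_P`, each first scaled by
#' [temperature_factor()] at the supplied temperature.
#'
#' @param Thd,Pi,Thy,R1P Concentrations (mM), all non-negative.
#' @param Enz0 Total enzyme concentration (same unit the user supplies
#'   throughout, e.g. mg/mL), strictly positive.
#' @param params Named vector with `K_M_S`, `K_M_P`, `k_catf`, `k_catr`,
#'   `T_max`, `T_width`.
#' @param temp Reaction temperature (degrees C); defaults to `T_max`
#'   (temperature factor 1).
#' @return Net rate `v` (positive in the phosphorolysis direction).
#' @export
phosphorolysis_rate <- function(Thd, Pi, Thy, R1P, Enz0, params,
                                temp = params[["T_max"]]) {
  stopifnot(Thd >= 0, Pi >= 0, Thy >= 0, R1P >= 0, Enz0 > 0)
  phos_rate_unchecked(Thd, Pi, Thy, R1P, Enz0, params, temp)
}

# rate law without the non-negativity preconditions: the integrator's
# trial steps may probe states a rounding error below zero
phos_rate_unchecked <- function(Thd, Pi, Thy, R1P, Enz0, params, temp) {
  k <- phos_elementary_rates(params, temp)
  denom <- k$k1 * Thd * Pi + k$km2 * Thy * R1P + k$km1 + k$k2
  if (denom <= 0) {
    stop("phosphorolysis rate denominator is not positive; ",
         "invalid parameterization")
  }
  Enz0 * (k$k1 * k$k2 * Thd * Pi - k$km1 * k$km2 * Thy * R1P) / denom
}

# elementary rates (k1, k-1, k2, k-2) from the Michaelis parameterization,
# each passed through the temperature factor
phos_elementary_rates <- function(params, temp) {
  tf <- temperature_factor(1, temp, params[["T_max"]], params[["T_width"]])
  ksum <- params[["k_catr"]] + params[["k_catf"]]
  list(k1 = ksum / params[["K_M_S"]] * tf,
       km1 = params[["k_catr"]] * tf,
       k2 = params[["k_catf"]] * tf,
       km2 = ksum / params[["K_M_P"]] * tf)
}

#' The built-in reversible phosphorolysis model
#'
#' Batch conversion of thymidine (`Thd`) plus inorganic phosphate (`Pi`)
#' into thymine (`Thy`) and pentose-1-phosphate (`R1P`) by a thermostable
#' nucleoside phosphorylase. States are the four concentrations (mM);
#' the six kinetic parameters are `K_M_S`, `K_M_P`, `k_catf`, `k_catr`,
#' `T_max`, `T_width`. Enzyme load (`Enz0`) and temperature (`temp`) are
#' experiment inputs, not estimated states.
#'
#' @param observe `"states"` (default) observes all four concentrations;
#'   `"conversion"` observes the single conversion percentage
#'   `100 * Thy / (Thy + Thd)` (see [conversion_percent()]).
#' @return A [kinetic_model].
#' @export
phosphorolysis_model <- function(observe = c("states", "conversion")) {
  observe <- match.arg(observe)
  rhs <- function(state, inputs, params, time) {
    v <- phos_rate_unchecked(state[[1]], state[[2]], state[[3]], state[[4]],
                             Enz0 = inputs[["Enz0"]], params = params,
                             temp = inputs[["temp"]])
    c(-v, -v, v, v)
  }
  if (observe == "states") {
    observation <- NULL
    obs_names <- c("Thd", "Pi", "Thy", "R1P")
    obs_jac <- NULL
  } else {
    observation <- function(state)
      c(conversion = conversion_percent(state[[3]], state[[1]]))
    obs_names <- "conversion"
    obs_jac <- function(state) {
      Thd <- state[[1]]; Thy <- state[[3]]
      tot <- Thd + Thy
      matrix(c(-100 * Thy / tot^2, 0, 100 * Thd / tot^2, 0), 1, 4,
             dimnames = list("conversion", c("Thd", "Pi", "Thy", "R1P")))
    }
  }
  kinetic_model(
    name = "phosphorolysis",
    state_names = c("Thd", "Pi", "Thy", "R1P"),
    parameter_names = c("K_M_S", "K_M_P", "k_catf", "k_catr",
                        "T_max", "T_width"),
    rhs = rhs,
    observation = observation,
    obs_names = obs_names,
    obs_jac = obs_jac,
    default_bounds = list(K_M_S = c(1e-3, 1e3), K_M_P = c(1e-3, 1e3),
                          k_catf = c(1e-2, 1e4), k_catr = c(1e-2, 1e4),
                          T_max = c(20, 90), T_width = c(1, 50)),
    compiled = list(
      func = "phos_derivs", initfunc = "phos_init",
      pack_parms = function(params, inputs)
        c(params[["K_M_S"]], params[["K_M_P"]], params[["k_catf"]],
          params[["k_catr"]], params[["T_max"]], params[["T_width"]],
          inputs[["Enz0"]], inputs[["temp"]])),
    units = list(concentration = "mM", time = "h", temperature = "degC"))
}

#' Conversion percentage
#'
#' Product fraction of the substrate/product pool,
#' `100 * c_product / (c_product + c_substrate)`.
#'
#' @param c_product,c_substrate Concentrations (same unit), not both zero.
#' @return Conversion in percent, in `[0, 100]`.
#' @examples
#' conversion_percent(1, 1)  # 50
#' @export
conversion_percent <- function(c_product, c_substrate) {
  if (any(c_product + c_substrate <= 0)) {
    stop("conversion undefined: product and substrate are both zero")
  }
  100 * c_product / (c_product + c_substrate)
}

#' Retrieve a built-in model by name
#'
#' @param name One of `"michaelis_menten"` or `"phosphorolysis"`.
#' @param ... Passed to the model constructor (e.g. `observe` for the
#'   phosphorolysis model).
#' @return A [kinetic_model].
#' @export
get_model <- function(name, ...) {
  registry <- list(michaelis_menten = mm_model,
                   phosphorolysis = phosphorolysis_model)
  if (!name %in% names(registry)) {
    stop("unknown model '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  }
  registry[[name]](...)
}

#' @rdname get_model
#' @export
list_models <- function() c("michaelis_menten", "phosphorolysis")
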