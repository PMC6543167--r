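#' Describe an experiment design
#'
#' The design vector holds everything that defines a prospective batch
#' experiment: the sampling times, the initial state, the constant
#' inputs (e.g. enzyme load and temperature) and the horizon. In the
#' sampling-time-optimization workflow the sampling times are the only
#' free entries.
#'
#' @param sampling_times Strictly increasing times (h) in `[0, t_end]`.
#' @param x0 Named initial state vector (all model states).
#' @param u Named vector of constant inputs; may be `NULL` for models
#'   without inputs.
#' @param t_end Experiment horizon (h); defaults to the last sampling time.
#' @return An object of class `design_vector`.
#' @export
design_vector <- function(sampling_times, x0, u = NULL,
                          t_end = max(sampling_times)) {
  sampling_times <- as.numeric(sampling_times)
  if (any(sampling_times < 0) || any(sampling_times > t_end)) {
    stop("sampling times must lie in [0, t_end]")
  }
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    stop("sampling times must be strictly increasing")
  }
  structure(list(sampling_times = sampling_times, x0 = x0, u = u,
                 t_end = t_end),
            class = "design_vector")
}

#' @export
print.design_vector <- function(x, ...) {
  cat("<design_vector> times:", paste(signif(x$sampling_times, 4),
                                      collapse = ", "),
      " t_end:", x$t_end, "\n")
  cat("  x0:", paste(names(x$x0), signif(unname(x$x0), 5),
                     sep = "=", collapse = ", "), "\n")
  if (!is.null(x$u))
    cat("  u: ", paste(names(x$u), signif(unname(x$u), 5),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# integration tolerances used everywhere (relative, absolute)
.mbdoe_rtol <- 1e-8
.mbdoe_atol <- 1e-10

#' Simulate a kinetic model
#'
#' Integrates the model ODEs from `t = 0` with the design's initial
#' state and inputs, and returns states and observables at the requested
#' times. Uses the stiffness-switching `lsoda` integrator (BDF-capable)
#' at relative tolerance 1e-8 and absolute tolerance 1e-10; built-in
#' models dispatch to their compiled right-hand side.
#'
#' @param model A [kinetic_model].
#' @param params Named numeric vector of kinetic parameters.
#' @param design A [design_vector]; `design$x0` may be overridden via the
#'   `x0` argument.
#' @param eval_times Times at which to report the solution; defaults to
#'   the design's sampling times. Must lie in `[0, t_end]`.
#' @param x0 Optional initial-state override (named, full state vector).
#' @param use_compiled Set `FALSE` to force the R-level right-hand side
#'   (used in tests to cross-check the compiled code).
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (time x state matrix) and `observables` (time x observable matrix).
#' @export
simulate_model <- function(model, params, design,
                           eval_times = design$sampling_times,
                           x0 = NULL, use_compiled = TRUE,
                           rtol = .mbdoe_rtol, atol = .mbdoe_atol) {
  stopifnot(inherits(model, "kinetic_model"))
  eval_times <- as.numeric(eval_times)
  if (any(eval_times < 0) || any(eval_times > design$t_end + 1e-12)) {
    stop("eval_times must lie within [0, t_end]")
  }
  if (is.null(x0)) x0 <- design$x0
  x0 <- x0[model$state_names]
  if (anyNA(x0)) stop("initial state must name every model state")

  times <- sort(unique(c(0, eval_times)))
  if (length(times) == 1L) {
    states <- matrix(x0, 1, length(x0),
                     dimnames = list(NULL, model$state_names))
  } else {
    states <- integrate_ode(model, params, design$u, x0, times, use_compiled,
                            rtol = rtol, atol = atol)
  }
  # map back to the requested times (with duplicates, any order)
  idx <- match_times(eval_times, times)
  states <- states[idx, , drop = FALSE]
  if (isTRUE(model$obs_identity)) {
    obs <- states
  } else {
    obs <- t(apply(states, 1L, model$observation))
    if (length(model$obs_names) == 1L) obs <- matrix(obs, ncol = 1L)
  }
  colnames(obs) <- model$obs_names
  structure(list(times = eval_times, states = states, observables = obs),
            class = "trajectory")
}

# low-level deSolve call returning the state matrix at `times`
# (first entry must be 0)
integrate_ode <- function(model, params, inputs, x0, times, use_compiled,
                          rtol = .mbdoe_rtol, atol = .mbdoe_atol) {
  if (use_compiled && !is.null(model$compiled)) {
    parms <- as.double(model$compiled$pack_parms(params, inputs))
    sol <- deSolve::ode(y = as.double(unname(x0)), times = times,
                        func = model$compiled$func,
                        parms = parms, dllname = "mbdoe",
                        initfunc = model$compiled$initfunc,
                        rtol = rtol, atol = atol)
  } else {
    f <- function(t, y, p) list(model$rhs(y, inputs, p, t))
    sol <- deSolve::ode(y = as.double(unname(x0)), times = times, func = f,
                        parms = params, rtol = rtol, atol = atol)
  }
  if (nrow(sol) < length(times) || anyNA(sol)) {
    last_t <- if (nrow(sol)) sol[nrow(sol), 1L] else times[1L]
    stop("ODE integration failed; last successful time ", last_t)
  }
  states <- sol[, -1L, drop = FALSE]
  dimnames(states) <- list(NULL, model$state_names)
  states
}

# index of each `wanted` time in the `grid` vector (exact doubles come
# from the same source; allow tiny numerical slack)
match_times <- function(wanted, grid) {
  idx <- vapply(wanted, function(t) {
    j <- which.min(abs(grid - t))
    if (abs(grid[j] - t) > 1e-9) stop("time ", t, " not on solution grid")
    j
  }, integer(1))
  idx
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, observables: ",
      paste(colnames(x$observables), collapse = ", "), "\n", sep = "")
  print(utils::head(cbind(time = x$times, x$observables)))
  invisible(x)
}

#' Output sensitivities with respect to the kinetic parameters
#'
#' Computes \eqn{\partial y_j(t_i) / \partial \theta_k} for the free
#' (non-fixed) parameters. The default method integrates the forward
#' sensitivity equations
#' \eqn{\dot S_x = J_x S_x + J_\theta} jointly with the states, using the
#' model's analytic Jacobians when available and central finite
#' differences of the right-hand side otherwise; `method = "fd"` instead
#' differentiates entire trajectories by central differences (relative
#' step 1e-6 scaled by `max(|theta|, 1)`) and serves as an independent
#' cross-check.
#'
#' @inheritParams simulate_model
#' @param free Names of the parameters to differentiate with respect to
#'   (defaults to all model parameters). Fixed parameters are simply
#'   omitted from this vector and never appear in the result.
#' @param method `"forward"` (sensitivity ODEs, default) or `"fd"`
#'   (trajectory-level central finite differences).
#' @return A 3-d array `time x observable x parameter` with dimnames,
#'   of class `sensitivity_matrix`.
#' @export
sensitivities <- function(model, params, design,
                          eval_times = design$sampling_times,
                          free = model$parameter_names,
                          method = c("forward", "fd"), x0 = NULL) {
  method <- match.arg(method)
  stopifnot(all(free %in% model$parameter_names))
  if (is.null(x0)) x0 <- design$x0
  x0 <- x0[model$state_names]
  eval_times <- as.numeric(eval_times)
  n_obs <- length(model$obs_names)
  out <- array(0, dim = c(length(eval_times), n_obs, length(free)),
               dimnames = list(NULL, model$obs_names, free))

  if (method == "fd") {
    # the finite differences must be resolved above the integration
    # error, so the oracle trajectories use tighter tolerances
    for (k in seq_along(free)) {
      h <- 1e-6 * max(abs(params[[free[k]]]), 1)
      up <- params; up[[free[k]]] <- params[[free[k]]] + h
      dn <- params; dn[[free[k]]] <- params[[free[k]]] - h
      y_up <- simulate_model(model, up, design, eval_times, x0 = x0,
                             rtol = 1e-12, atol = 1e-13)$observables
      y_dn <- simulate_model(model, dn, design, eval_times, x0 = x0,
                             rtol = 1e-12, atol = 1e-13)$observables
      out[, , k] <- (y_up - y_dn) / (2 * h)
    }
  } else {
    out[] <- forward_sensitivities(model, params, design, eval_times,
                                   free, x0)
  }
  class(out) <- c("sensitivity_matrix", class(out))
  out
}

# integrate the augmented (state + sensitivity) system
forward_sensitivities <- function(model, params, design, eval_times,
                                  free, x0) {
  n <- length(model$state_names)
  k <- length(free)
  free_idx <- match(free, model$parameter_names)
  inputs <- design$u

  jac_x <- model$jac_state %||% function(state, inputs, params, time)
    fd_jacobian(function(s) model$rhs(s, inputs, params, time), state)
  jac_p_full <- model$jac_params %||% function(state, inputs, params, time)
    fd_jacobian(function(p) {
      pp <- params; pp[seq_along(p)] <- p
      names(pp) <- names(params)
      model$rhs(state, inputs, pp, time)
    }, params[model$parameter_names])

  aug <- function(t, y, p) {
    x <- y[seq_len(n)]
    Sx <- matrix(y[-seq_len(n)], n, k)
    dx <- model$rhs(x, inputs, p, t)
    Jx <- jac_x(x, inputs, p, t)
    Jp <- jac_p_full(x, inputs, p, t)[, free_idx, drop = FALSE]
    list(c(dx, as.vector(Jx %*% Sx + Jp)))
  }

  times <- sort(unique(c(0, eval_times)))
  y0 <- c(unname(x0), rep(0, n * k))
  sol <- deSolve::ode(y = y0, times = times, func = aug, parms = params,
                      rtol = .mbdoe_rtol, atol = .mbdoe_atol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    stop("sensitivity integration failed")
  }
  idx <- match_times(eval_times, times)

  n_obs <- length(model$obs_names)
  obs_jac <- model$obs_jac %||% function(state)
    fd_jacobian(model$observation, state)
  out <- array(0, dim = c(length(eval_times), n_obs, k))
  for (i in seq_along(idx)) {
    row <- sol[idx[i], -1L]
    x <- row[seq_len(n)]
    Sx <- matrix(row[-seq_len(n)], n, k)
    G <- obs_jac(x)
    out[i, , ] <- G %*% Sx
  }
  out
}

# central-difference Jacobian of a vector-valued function
fd_jacobian <- function(f, x, rel_step = 1e-6) {
  x <- as.numeric(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(abs(x[j]), 1)
    up <- x; up[j] <- x[j] + h
    dn <- x; dn[j] <- x[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory as tidy long-format data
#'
#' @param traj A `trajectory`.
#' @return Data frame with columns `time`, `name`, `value` (observables).
#' @export
trajectory_to_df <- function(traj) {
  obs <- traj$observables
  data.frame(time = rep(traj$times, ncol(obs)),
             name = rep(colnames(obs), each = nrow(obs)),
             value = as.vector(obs),
             stringsAsFactors = FALSE)
}

#' Export a sensitivity array as tidy long-format data
#'
#' @param sens A `sensitivity_matrix` (3-d array).
#' @param times The evaluation times the array was computed at.
#' @return Data frame with columns `time`, `observable`, `parameter`,
#'   `value`.
#' @export
sensitivities_to_df <- function(sens, times) {
  d <- dim(sens)
  dn <- dimnames(sens)
  expand <- expand.grid(time = seq_len(d[1]), observable = dn[[2]],
                        parameter = dn[[3]], stringsAsFactors = FALSE)
  data.frame(time = times[expand$time],
             observable = expand$observable,
             parameter = expand$parameter,
             value = as.vector(sens),
             stringsAsFactors = FALSE)
}
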