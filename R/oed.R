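#' Set up a sampling-time design problem
#'
#' Describes the optimization of an experiment's sampling times at a
#' nominal parameter vector. FIM-based criteria (`D`, `E`, `A`) score a
#' candidate design through the information matrix of its sensitivities;
#' the Monte-Carlo `Q` criterion scores it by actually re-estimating the
#' parameters on perturbed synthetic data generated at those times.
#'
#' @param model A [kinetic_model].
#' @param theta Nominal kinetic parameters (named).
#' @param design_template A [design_vector] supplying `x0`, `u` and
#'   `t_end`; its sampling times are ignored (they are the decision
#'   variables).
#' @param criterion One of `"D"`, `"E"`, `"A"`, `"Q"`.
#' @param noise_sigma Measurement noise standard deviation (scalar or
#'   per observable), used for the FIM's noise covariance and for the
#'   Monte-Carlo perturbations.
#' @param time_bounds `c(lower, upper)` for every sampling time
#'   (defaults to `[0.01, t_end]`).
#' @param n_times Number of sampling times being optimized.
#' @param mc For `criterion = "Q"`: list with `n` (replicates per
#'   evaluation, default 500) and `seed`. The same seed is reused for
#'   every candidate design (common random numbers), which makes the
#'   Q-objective deterministic per problem.
#' @param fit_bounds Bounds for the re-estimated parameters in the
#'   Monte-Carlo refits (default: the model's default bounds for the
#'   parameters in `theta`).
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(model, theta, design_template,
                           criterion = c("A", "D", "E", "Q"),
                           noise_sigma, time_bounds = NULL,
                           n_times = 2L, mc = list(n = 500, seed = 1),
                           fit_bounds = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(time_bounds)) time_bounds <- c(0.01, design_template$t_end)
  if (is.null(fit_bounds)) {
    fit_bounds <- model$default_bounds[names(theta)]
  }
  mc <- utils::modifyList(list(n = 500, seed = 1), mc)
  structure(list(model = model, theta = theta,
                 template = design_template, criterion = criterion,
                 noise_sigma = noise_sigma, time_bounds = time_bounds,
                 n_times = as.integer(n_times), mc = mc,
                 fit_bounds = fit_bounds),
            class = "design_problem")
}

#' Score a candidate set of sampling times
#'
#' Returns the criterion value sign-adjusted so that lower is always
#' better (`-D`, `-E`, `A`, `Q`). For the FIM criteria the sensitivities
#' are simulated at the candidate times and the information matrix
#' assembled with the problem's noise covariance. For `Q`, noiseless
#' synthetic data is generated at the candidate times and a Monte-Carlo
#' ensemble (common random numbers across candidates) is re-estimated.
#'
#' @param problem A [design_problem()].
#' @param times Candidate sampling times (within bounds; they are
#'   sorted internally, the criteria being symmetric in the times).
#' @return Scalar criterion value (lower is better).
#' @export
evaluate_design <- function(problem, times) {
  times <- sort(as.numeric(times))
  lb <- problem$time_bounds[1]; ub <- problem$time_bounds[2]
  if (any(times < lb - 1e-9) || any(times > ub + 1e-9)) {
    stop("candidate times violate the bounds [", lb, ", ", ub, "]")
  }
  times <- unique(pmin(pmax(times, lb), ub))
  design <- design_vector(times, x0 = problem$template$x0,
                          u = problem$template$u,
                          t_end = problem$template$t_end)
  if (problem$criterion == "Q") {
    base <- generate_synthetic(problem$model, problem$theta, design,
                               noise_sd = 0, seed = problem$mc$seed,
                               sigma_report = problem$noise_sigma)
    ens <- run_ensemble(problem$model, base,
                        noise_sigma = problem$noise_sigma,
                        n = problem$mc$n, seed = problem$mc$seed,
                        fit_options = list(bounds = problem$fit_bounds,
                                           theta0 = problem$theta))
    return(q_criterion(ens))
  }
  sens <- sensitivities(problem$model, problem$theta, design,
                        eval_times = times)
  fim <- compute_fim(sens, noise_cov = problem$noise_sigma^2)
  switch(problem$criterion,
         D = -fim$criteria$D,
         E = -fim$criteria$E,
         A = fim_criterion(fim$fim, "A"))
}

#' Optimize the sampling times of an experiment
#'
#' Minimizes the (sign-adjusted) design criterion over the sampling
#' times with a bounded Nelder-Mead simplex search: candidates are
#' clamped to the time bounds and sorted before evaluation, which keeps
#' the ordering constraint satisfied. The search stops when the
#' relative change of the best criterion value is below `rel_tol` over
#' 5 consecutive outer iterations, or after `max_iter` iterations.
#' Every evaluation is recorded in the trace; with the Q-criterion the
#' per-problem Monte-Carlo seed is frozen (common random numbers), so
#' the whole optimization is deterministic.
#'
#' @param problem A [design_problem()].
#' @param initial_times Feasible starting times.
#' @param max_iter Maximum number of outer iterations (default 50).
#' @param rel_tol Relative-change convergence tolerance (default 1e-3).
#' @return List with `times` (the best design found, sorted),
#'   `criterion` (its sign-adjusted value), `converged`, `iterations`,
#'   `converged_at` (first iteration at which the stopping rule held)
#'   and `trace` (data frame: iteration, evaluation index, candidate
#'   times, value, accepted flag).
#' @export
optimize_design <- function(problem, initial_times, max_iter = 50,
                            rel_tol = 1e-3) {
  lb <- problem$time_bounds[1]; ub <- problem$time_bounds[2]
  x0 <- sort(pmin(pmax(as.numeric(initial_times), lb), ub))
  k <- length(x0)

  trace <- new.env(parent = emptyenv())
  trace$rows <- list()
  trace$best <- Inf
  trace$iter <- 0L
  fwrap <- function(x) {
    x <- sort(pmin(pmax(x, lb), ub))
    val <- evaluate_design(problem, x)
    accepted <- val < trace$best
    if (accepted) trace$best <- val
    trace$rows[[length(trace$rows) + 1L]] <-
      c(iteration = trace$iter, x, value = val,
        accepted = as.numeric(accepted))
    val
  }

  # Nelder-Mead with explicit outer iterations so convergence can be
  # assessed per iteration
  simplex <- rbind(x0, t(vapply(seq_len(k), function(j) {
    v <- x0
    step <- 0.1 * (ub - lb)
    v[j] <- if (v[j] + step <= ub) v[j] + step else v[j] - step
    v
  }, numeric(k))))
  fvals <- apply(simplex, 1L, fwrap)

  best_hist <- min(fvals)
  converged_at <- NA_integer_
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma_nm <- 0.5
  for (it in seq_len(max_iter)) {
    trace$iter <- it
    ord <- order(fvals)
    simplex <- simplex[ord, , drop = FALSE]
    fvals <- fvals[ord]
    centroid <- colMeans(simplex[-nrow(simplex), , drop = FALSE])
    worst <- simplex[nrow(simplex), ]

    xr <- centroid + alpha * (centroid - worst)
    fr <- fwrap(xr)
    if (fr < fvals[1]) {
      xe <- centroid + gamma * (xr - centroid)
      fe <- fwrap(xe)
      if (fe < fr) { simplex[nrow(simplex), ] <- xe; fvals[length(fvals)] <- fe }
      else { simplex[nrow(simplex), ] <- xr; fvals[length(fvals)] <- fr }
    } else if (fr < fvals[length(fvals) - 1L]) {
      simplex[nrow(simplex), ] <- xr; fvals[length(fvals)] <- fr
    } else {
      xc <- centroid + rho * (worst - centroid)
      fc <- fwrap(xc)
      if (fc < fvals[length(fvals)]) {
        simplex[nrow(simplex), ] <- xc; fvals[length(fvals)] <- fc
      } else {
        for (j in 2:nrow(simplex)) {
          simplex[j, ] <- simplex[1, ] + sigma_nm * (simplex[j, ] - simplex[1, ])
          fvals[j] <- fwrap(simplex[j, ])
        }
      }
    }
    best_hist <- c(best_hist, min(fvals))
    n_h <- length(best_hist)
    if (is.na(converged_at) && n_h >= 6L) {
      recent <- best_hist[(n_h - 5L):n_h]
      rel <- abs(diff(recent)) / pmax(abs(recent[-length(recent)]), 1e-12)
      if (all(rel < rel_tol)) converged_at <- it
    }
    if (!is.na(converged_at)) break
  }

  rows <- do.call(rbind, trace$rows)
  tr_df <- as.data.frame(rows)
  names(tr_df) <- c("iteration", paste0("t", seq_len(k)), "value",
                    "accepted")
  tr_df$evaluation <- seq_len(nrow(tr_df))
  tr_df$accepted <- tr_df$accepted > 0

  best_idx <- which.min(tr_df$value)
  best_times <- sort(as.numeric(tr_df[best_idx, paste0("t", seq_len(k))]))
  list(times = best_times,
       criterion = tr_df$value[best_idx],
       converged = !is.na(converged_at),
       iterations = if (is.na(converged_at)) max_iter else converged_at,
       converged_at = converged_at,
       trace = tr_df)
}
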