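#' Bundle measurements with their experiment designs
#'
#' @param records Data frame with columns `experiment`, `time` (h),
#'   `observable`, `value`, `sigma` (standard deviation of the
#'   measurement error, strictly positive).
#' @param designs Either a single [design_vector] (applied to every
#'   experiment) or a named list keyed by experiment id.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(records, designs) {
  required <- c("experiment", "time", "observable", "value", "sigma")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("no records")
  for (col in c("time", "value", "sigma")) {
    if (!is.numeric(records[[col]]) || anyNA(records[[col]])) {
      stop("column '", col, "' must be numeric without missing values")
    }
  }
  bad <- which(records$sigma <= 0)
  if (length(bad)) {
    stop("sigma must be > 0; offending row(s): ",
         paste(bad, collapse = ", "))
  }
  records$experiment <- as.character(records$experiment)
  ids <- unique(records$experiment)
  if (inherits(designs, "design_vector")) {
    designs <- stats::setNames(rep(list(designs), length(ids)), ids)
  }
  if (!all(ids %in% names(designs))) {
    stop("no design for experiment(s): ",
         paste(setdiff(ids, names(designs)), collapse = ", "))
  }
  for (id in ids) {
    tmax <- designs[[id]]$t_end
    out_of_range <- records$experiment == id &
      (records$time < 0 | records$time > tmax)
    if (any(out_of_range)) {
      stop("experiment ", id, ": measurement times outside [0, ",
           tmax, "]")
    }
  }
  structure(list(records = records, designs = designs[ids]),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set> ", nrow(x$records), " records, ",
      length(x$designs), " experiment(s)\n", sep = "")
  print(utils::head(x$records))
  invisible(x)
}

# split a free-parameter vector into kinetic parameters and
# initial-state overrides ("<state>0" naming convention)
split_theta <- function(theta, model) {
  kin <- intersect(names(theta), model$parameter_names)
  x0_names <- paste0(model$state_names, "0")
  init <- intersect(names(theta), x0_names)
  unknown <- setdiff(names(theta), c(kin, init))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  list(kinetic = theta[kin],
       x0 = stats::setNames(theta[init],
                            sub("0$", "", init)))
}

# full kinetic parameter vector from free + fixed parts
assemble_params <- function(theta_split, fixed, model) {
  params <- c(theta_split$kinetic,
              unlist(fixed[intersect(names(fixed), model$parameter_names)]))
  missing_p <- setdiff(model$parameter_names, names(params))
  if (length(missing_p)) {
    stop("parameter(s) neither free nor fixed: ",
         paste(missing_p, collapse = ", "))
  }
  params[model$parameter_names]
}

#' Weighted least-squares objective
#'
#' The maximum-likelihood criterion for Gaussian iid measurement error:
#' per experiment, the squared residuals are divided by the per-record
#' variances `sigma^2` and by the number of records in that experiment,
#' then summed over experiments:
#' \deqn{J = \sum_{exp} \frac{1}{n_{mes}} \sum_k
#'       \frac{(y_k(\theta) - \hat y_k)^2}{\sigma_k^2}.}
#' When every record shares one variance this reduces to the single
#' `1/sigma^2` prefactor form. A failed simulation returns `+Inf` (with
#' the cause attached as an attribute) so optimizers can move away.
#'
#' @param model A [kinetic_model].
#' @param theta Named vector of free parameters; kinetic parameters by
#'   name, initial states by `"<state>0"` (e.g. `S0`).
#' @param data A [measurement_set].
#' @param fixed Named list/vector of parameters held constant.
#' @return The scalar objective `J >= 0`.
#' @export
wls_objective <- function(model, theta, data, fixed = NULL) {
  sp <- split_theta(theta, model)
  params <- assemble_params(sp, fixed, model)
  J <- 0
  for (id in names(data$designs)) {
    design <- data$designs[[id]]
    x0 <- design$x0
    x0[names(sp$x0)] <- sp$x0
    rec <- data$records[data$records$experiment == id, , drop = FALSE]
    pred <- tryCatch(
      simulate_model(model, params, design, eval_times = rec$time, x0 = x0),
      error = function(e) e)
    if (inherits(pred, "error")) {
      out <- Inf
      attr(out, "cause") <- conditionMessage(pred)
      return(out)
    }
    obs_idx <- match(rec$observable, colnames(pred$observables))
    if (anyNA(obs_idx)) {
      stop("unknown observable(s): ",
           paste(unique(rec$observable[is.na(obs_idx)]), collapse = ", "))
    }
    yhat <- pred$observables[cbind(seq_len(nrow(rec)), obs_idx)]
    J <- J + sum((yhat - rec$value)^2 / rec$sigma^2) / nrow(rec)
  }
  J
}

#' Latin hypercube start values
#'
#' Draws `n` stratified points from the box given by `bounds`: in every
#' parameter dimension exactly one draw falls in each of the `n`
#' equal-width bins. Used to seed multistart optimization.
#'
#' @param bounds Named list of finite `c(lower, upper)` intervals.
#' @param n Number of starts, `>= 1`.
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return An `n x p` matrix with one start per row, columns named after
#'   the parameters.
#' @export
lhs_starts <- function(bounds, n, seed) {
  stopifnot(n >= 1)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (!all(is.finite(lo)) || !all(is.finite(hi)) || any(hi <= lo)) {
    stop("bounds must be finite intervals with lower < upper")
  }
  u <- withr::with_seed(seed, lhs::randomLHS(n, length(bounds)))
  pts <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
  colnames(pts) <- names(bounds)
  pts
}

# log10 transform for strictly positive parameters (conditioning of
# rate constants spanning decades); linear otherwise
make_transform <- function(bounds) {
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  use_log <- lo > 0
  list(
    use_log = use_log,
    to = function(x) {
      z <- x
      z[use_log] <- log10(x[use_log])
      z
    },
    from = function(z) {
      x <- z
      x[use_log] <- 10^z[use_log]
      x
    })
}

# Precompiled weighted-residual closure: theta (free, named) -> vector of
# (predicted - observed) / (sigma * sqrt(n_mes)), so that the sum of
# squares equals the weighted least-squares objective. All record
# bookkeeping is resolved once, outside the optimization hot loop.
make_residual_fn <- function(model, data, fixed, free) {
  kin_free <- intersect(free, model$parameter_names)
  x0_free <- intersect(free, paste0(model$state_names, "0"))
  unknown <- setdiff(free, c(kin_free, x0_free))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  fixed_kin <- unlist(fixed[intersect(names(fixed), model$parameter_names)])
  missing_p <- setdiff(model$parameter_names, c(kin_free, names(fixed_kin)))
  if (length(missing_p)) {
    stop("parameter(s) neither free nor fixed: ",
         paste(missing_p, collapse = ", "))
  }
  x0_states <- sub("0$", "", x0_free)
  p_order <- model$parameter_names

  exps <- lapply(names(data$designs), function(id) {
    sel <- data$records$experiment == id
    rec <- data$records[sel, , drop = FALSE]
    obs_idx <- match(rec$observable, model$obs_names)
    if (anyNA(obs_idx)) {
      stop("unknown observable(s): ",
           paste(unique(rec$observable[is.na(obs_idx)]), collapse = ", "))
    }
    list(design = data$designs[[id]], times = rec$time,
         obs_idx = obs_idx, value = rec$value,
         w = 1 / (rec$sigma * sqrt(nrow(rec))))
  })

  function(theta) {
    params <- c(theta[kin_free], fixed_kin)[p_order]
    res <- lapply(exps, function(e) {
      x0 <- e$design$x0
      x0[x0_states] <- theta[x0_free]
      pred <- tryCatch(
        simulate_model(model, params, e$design, eval_times = e$times,
                       x0 = x0),
        error = function(err) NULL)
      if (is.null(pred)) return(rep(1e8, length(e$value)))
      yhat <- pred$observables[cbind(seq_along(e$times), e$obs_idx)]
      (yhat - e$value) * e$w
    })
    unlist(res, use.names = FALSE)
  }
}

#' Fit model parameters by multistart weighted least squares
#'
#' Minimizes the weighted least-squares objective ([wls_objective()])
#' with bounded Levenberg-Marquardt local searches
#' ([minpack.lm::nls.lm()] on the weighted residual vector) from
#' `n_starts` Latin-hypercube starting points, keeping the best
#' solution. Strictly positive parameters are optimized in log10 space
#' (rate constants span decades; the transform conditions the problem).
#' Parameters listed in `fixed` are held at their value exactly and
#' never appear in the result. Ties in the objective (within 1e-10)
#' prefer converged runs, then the lexicographically smallest parameter
#' vector, so the result is deterministic.
#'
#' @inheritParams wls_objective
#' @param bounds Named list of `c(lower, upper)` for every free
#'   parameter (kinetic parameters and/or `"<state>0"` initial states).
#' @param fixed Named list of parameters held constant.
#' @param n_starts Number of Latin-hypercube starts (default 50).
#' @param seed Integer seed for the start draws.
#' @param start Optional matrix/vector of explicit starts (overrides the
#'   LHS draws; used for warm starting).
#' @param control Passed to [minpack.lm::nls.lm.control()] (default:
#'   at most 200 iterations per start).
#' @return An object of class `fit_result` with elements `theta_hat`,
#'   `objective`, `converged`, `n_starts`, `start_values`, `per_start`
#'   (one row per start: start values, objective, convergence info) and
#'   `residuals`.
#' @export
fit_parameters <- function(model, data, bounds, fixed = NULL,
                           n_starts = 50, seed = 1, start = NULL,
                           control = list()) {
  stopifnot(inherits(data, "measurement_set"))
  free <- names(bounds)
  n_free <- length(free)
  if (nrow(data$records) < n_free) {
    warning("fewer records (", nrow(data$records), ") than free parameters (",
            n_free, "); the fit is under-determined")
  }
  if (is.null(start)) {
    start <- lhs_starts(bounds, n_starts, seed)
  } else {
    if (is.null(dim(start))) start <- matrix(start, 1L,
                                             dimnames = list(NULL, names(start)))
    start <- start[, free, drop = FALSE]
  }
  n_starts <- nrow(start)

  tr <- make_transform(bounds)
  lo <- tr$to(vapply(bounds, `[`, numeric(1), 1L))
  hi <- tr$to(vapply(bounds, `[`, numeric(1), 2L))
  resid_fn <- make_residual_fn(model, data, fixed, free)
  resid_tr <- function(z) resid_fn(stats::setNames(tr$from(z), free))
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200), control))

  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    z0 <- pmin(pmax(tr$to(start[i, ]), lo), hi)
    res <- tryCatch(minpack.lm::nls.lm(z0, lower = lo, upper = hi,
                                       fn = resid_tr, control = ctrl),
                    error = function(e) e)
    if (inherits(res, "error")) {
      runs[[i]] <- list(theta = rep(NA_real_, n_free), objective = Inf,
                        info = NA_integer_,
                        message = conditionMessage(res))
    } else {
      runs[[i]] <- list(theta = stats::setNames(tr$from(res$par), free),
                        objective = sum(res$fvec^2),
                        info = res$info,
                        message = res$message)
    }
  }
  objectives <- vapply(runs, `[[`, numeric(1), "objective")
  converged_runs <- vapply(runs, function(r)
    isTRUE(r$info %in% 1:3), logical(1))
  if (all(!is.finite(objectives))) {
    stop("all starts failed: ",
         paste(unique(vapply(runs, `[[`, character(1), "message")),
               collapse = "; "))
  }
  # best objective; ties prefer converged runs, then lexicographically
  # smallest parameter vector
  best_J <- min(objectives)
  tied <- which(objectives <= best_J + 1e-10)
  if (length(tied) > 1L) {
    if (any(converged_runs[tied])) tied <- tied[converged_runs[tied]]
    thetas <- do.call(rbind, lapply(runs[tied], `[[`, "theta"))
    ord <- do.call(order, as.data.frame(thetas))
    best <- tied[ord[1L]]
  } else {
    best <- tied
  }
  theta_hat <- runs[[best]]$theta

  per_start <- data.frame(start, objective = objectives,
                          info = vapply(runs, function(r)
                            as.integer(r$info %||% NA_integer_),
                            integer(1)))
  res_df <- fit_residuals(model, theta_hat, data, fixed)
  structure(list(theta_hat = theta_hat,
                 objective = objectives[best],
                 converged = converged_runs[best],
                 n_starts = n_starts,
                 start_values = start,
                 per_start = per_start,
                 residuals = res_df,
                 bounds = bounds, fixed = fixed, seed = seed),
            class = "fit_result")
}

# per-record predictions and residuals at a parameter vector
fit_residuals <- function(model, theta, data, fixed = NULL) {
  sp <- split_theta(theta, model)
  params <- assemble_params(sp, fixed, model)
  out <- data$records
  out$predicted <- NA_real_
  for (id in names(data$designs)) {
    design <- data$designs[[id]]
    x0 <- design$x0
    x0[names(sp$x0)] <- sp$x0
    sel <- out$experiment == id
    pred <- simulate_model(model, params, design,
                           eval_times = out$time[sel], x0 = x0)
    obs_idx <- match(out$observable[sel], colnames(pred$observables))
    out$predicted[sel] <- pred$observables[cbind(seq_len(sum(sel)), obs_idx)]
  }
  out$residual <- out$predicted - out$value
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> J =", format(x$objective, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(signif(x$theta_hat, 6))
  cat("  ", x$n_starts, "start(s);",
      sum(is.finite(x$per_start$objective)), "finished\n")
  invisible(x)
}
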