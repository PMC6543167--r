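#' Monte-Carlo re-estimation ensemble
#'
#' Draws the true (nonlinear) sampling distribution of the parameter
#' estimates by repeatedly perturbing the data with iid Gaussian noise
#' and refitting. Each replicate adds `N(0, noise_sigma^2)` to every
#' record value and re-estimates the free parameters, warm-started at
#' the base estimate (with a small Latin-hypercube fallback if the warm
#' start fails). Replicates receive deterministic per-replicate seeds
#' derived from the master seed, so the ensemble is reproducible and
#' independent of execution order.
#'
#' @param model A [kinetic_model].
#' @param base_data A [measurement_set] holding the unperturbed data.
#' @param noise_sigma Standard deviation of the perturbation: a scalar
#'   or a per-record vector.
#' @param n Number of replicates.
#' @param seed Master integer seed.
#' @param fit_options List with `bounds` (named, the free parameters to
#'   re-estimate), optional `fixed`, optional `theta0` (warm-start
#'   vector; fitted from the base data when absent) and optional
#'   `fallback_starts` (default 5).
#' @param mode `"data"` perturbs the recorded values as stored;
#'   `"synthetic"` first replaces them by the noiseless model prediction
#'   at the base estimate, so the perturbation is applied to the exact
#'   trajectory.
#' @return An object of class `mc_ensemble`: `thetas` (replicate x
#'   parameter matrix of converged re-estimates), `seeds`,
#'   `n_requested`, `n_converged`, `base_data`, `base_theta`,
#'   `noise_sigma`, `discarded` (per-failure reasons).
#' @export
run_ensemble <- function(model, base_data, noise_sigma, n, seed,
                         fit_options, mode = c("data", "synthetic")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  bounds <- fit_options$bounds
  fixed <- fit_options$fixed
  fallback_starts <- fit_options$fallback_starts %||% 5L

  theta0 <- fit_options$theta0
  if (is.null(theta0)) {
    theta0 <- fit_parameters(model, base_data, bounds, fixed = fixed,
                             n_starts = 25, seed = seed)$theta_hat
  }
  theta0 <- theta0[names(bounds)]

  data <- base_data
  if (mode == "synthetic") {
    base_pred <- fit_residuals(model, theta0, base_data, fixed)
    data$records$value <- base_pred$predicted
  }
  base_values <- data$records$value
  n_rec <- length(base_values)
  sig <- rep_len(noise_sigma, n_rec)

  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L, n))
  thetas <- matrix(NA_real_, n, length(bounds),
                   dimnames = list(NULL, names(bounds)))
  discarded <- list()
  for (r in seq_len(n)) {
    pert <- data
    if (any(sig > 0)) {
      eps <- withr::with_seed(rep_seeds[r], stats::rnorm(n_rec, 0, sig))
      pert$records$value <- base_values + eps
    }
    res <- refit_once(model, pert, bounds, fixed, theta0,
                      fallback_starts, rep_seeds[r])
    if (is.null(res)) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(replicate = r, reason = "did not converge")
    } else {
      thetas[r, ] <- res
    }
  }
  ok <- stats::complete.cases(thetas)
  if (sum(!ok) > 0.2 * n) {
    stop("more than 20% of Monte-Carlo replicates failed to converge (",
         sum(!ok), "/", n, "): the design is pathologically uninformative")
  }
  structure(list(thetas = thetas[ok, , drop = FALSE],
                 seeds = rep_seeds,
                 n_requested = n,
                 n_converged = sum(ok),
                 base_data = base_data,
                 base_theta = theta0,
                 noise_sigma = noise_sigma,
                 discarded = if (length(discarded))
                   do.call(rbind, discarded)
                 else data.frame(replicate = integer(), reason = character()),
                 mode = mode),
            class = "mc_ensemble")
}

# single-replicate refit: warm start, LHS fallback, NULL if unconverged
refit_once <- function(model, data, bounds, fixed, theta0,
                       fallback_starts, seed) {
  fit <- tryCatch(
    fit_parameters(model, data, bounds, fixed = fixed, start = theta0),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) return(fit$theta_hat)
  fit <- tryCatch(
    fit_parameters(model, data, bounds, fixed = fixed,
                   n_starts = fallback_starts, seed = seed),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) fit$theta_hat else NULL
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat("<mc_ensemble> ", x$n_converged, "/", x$n_requested,
      " converged replicates over ",
      paste(colnames(x$thetas), collapse = ", "), "\n", sep = "")
  print(signif(apply(x$thetas, 2, stats::quantile,
                     probs = c(0.1, 0.5, 0.9)), 5))
  invisible(x)
}

#' Fraction of Monte-Carlo estimates inside the FIM confidence region
#'
#' Compares the nonlinear Monte-Carlo sampling distribution with its
#' Gaussian (FIM) linearization: the fraction of ensemble rows whose
#' squared Mahalanobis distance from the base estimate — under the
#' Cramer-Rao covariance `FIM^-1` — is at most the chi-square quantile
#' at `level` with one degree of freedom per free parameter. For a
#' near-linear model this fraction approaches `level`; a clear deficit
#' signals that the true confidence region is not ellipsoidal.
#'
#' @param ensemble An [run_ensemble()] result.
#' @param fim_result A `fim_result` over the same free parameters.
#' @param level Confidence level (default 0.95).
#' @param center Ellipsoid center; defaults to the ensemble's base
#'   estimate.
#' @return The inside fraction (scalar in `[0, 1]`).
#' @export
coverage_vs_fim <- function(ensemble, fim_result, level = 0.95,
                            center = NULL) {
  p <- colnames(ensemble$thetas)
  if (!setequal(p, fim_result$parameters)) {
    stop("ensemble and FIM cover different parameters")
  }
  if (!fim_result$invertible) {
    stop("FIM non-invertible: no confidence ellipsoid ",
         "(consider the Q-criterion)")
  }
  if (is.null(center)) center <- ensemble$base_theta[p]
  d2 <- stats::mahalanobis(ensemble$thetas[, p, drop = FALSE],
                           center = as.numeric(center),
                           cov = fim_result$cov[p, p])
  mean(d2 <= stats::qchisq(level, df = length(p)))
}

#' Quantile-based design criterion (Q-criterion)
#'
#' A scalar measure of the spread of a Monte-Carlo parameter ensemble:
#' the sum over parameters of the squared width between the 90th and
#' 10th percentile,
#' \deqn{Q = \sum_i (Q_{\theta_i,0.9} - Q_{\theta_i,0.1})^2.}
#' Smaller is better. Because it needs only the Monte-Carlo sample it
#' remains available when the FIM is singular, and the quantile widths
#' make it robust to outlying replicates. Quantiles use linear
#' interpolation between order statistics at positions `(n-1)p + 1`
#' (type 7).
#'
#' @param thetas Replicate-by-parameter matrix (or a vector for a single
#'   parameter) with at least 2 rows; an `mc_ensemble` is also accepted.
#' @return The scalar criterion value, `>= 0`.
#' @export
q_criterion <- function(thetas) {
  if (inherits(thetas, "mc_ensemble")) thetas <- thetas$thetas
  if (is.null(dim(thetas))) thetas <- matrix(thetas, ncol = 1L)
  if (nrow(thetas) < 2L) stop("need at least 2 replicates")
  widths <- apply(thetas, 2L, function(x) {
    q <- stats::quantile(x, probs = c(0.1, 0.9), names = FALSE, type = 7)
    q[2L] - q[1L]
  })
  sum(widths^2)
}

#' Q-criterion of the FIM's own Gaussian linearization
#'
#' Draws `n` samples from the multivariate normal with mean `theta_hat`
#' and covariance `FIM^-1` and evaluates [q_criterion()] on them.
#' Comparing this with the Q-criterion of the true Monte-Carlo ensemble
#' exposes FIM-vs-Monte-Carlo disagreement: on near-linear designs the
#' two are close; on poor designs the FIM misstates the parameter
#' spread.
#'
#' @param fim_result An invertible `fim_result`.
#' @param theta_hat Center of the Gaussian (named as the FIM parameters).
#' @param n Number of draws (default 5000).
#' @param seed Integer seed.
#' @return The scalar Q value.
#' @export
q_criterion_from_fim <- function(fim_result, theta_hat, n = 5000, seed = 1) {
  if (!fim_result$invertible) {
    stop("FIM non-invertible: cannot sample its Gaussian linearization")
  }
  p <- fim_result$parameters
  L <- chol(fim_result$cov)
  z <- withr::with_seed(seed,
                        matrix(stats::rnorm(n * length(p)), n, length(p)))
  draws <- z %*% L
  draws <- sweep(draws, 2L, as.numeric(theta_hat[p]), `+`)
  colnames(draws) <- p
  q_criterion(draws)
}

#' Subsample robustness of the Q-criterion
#'
#' Recomputes the Q-criterion on `repeats` random subsamples (drawn
#' without replacement, `floor(fraction * n)` rows each) and returns the
#' values normalized by their mean. A narrow normalized distribution
#' means the criterion is stable under reduced sample size.
#'
#' @param thetas Replicate-by-parameter matrix or `mc_ensemble`.
#' @param fraction Subsample fraction in `(0, 1]` (default 0.8).
#' @param repeats Number of subsamples (default 500).
#' @param seed Integer seed.
#' @return Numeric vector of length `repeats` with mean exactly 1.
#' @export
robustness_subsample <- function(thetas, fraction = 0.8, repeats = 500,
                                 seed = 1) {
  if (inherits(thetas, "mc_ensemble")) thetas <- thetas$thetas
  stopifnot(fraction > 0, fraction <= 1, repeats >= 1)
  n <- nrow(thetas)
  m <- floor(fraction * n)
  qs <- withr::with_seed(seed, vapply(seq_len(repeats), function(i) {
    q_criterion(thetas[sample.int(n, m), , drop = FALSE])
  }, numeric(1)))
  qs / mean(qs)
}
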