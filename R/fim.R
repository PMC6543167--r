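#' Fisher information matrix from output sensitivities
#'
#' Accumulates \eqn{FIM = \sum_{exp} \sum_{t_i} S_i^\top \Sigma_i^{-1} S_i}
#' over experiments and sampling times, where \eqn{S_i} is the
#' observable-by-parameter sensitivity block at time \eqn{t_i} and
#' \eqn{\Sigma_i} the measurement-noise covariance at that time. The
#' inverse of the FIM is the Cramer-Rao lower bound on the covariance of
#' an unbiased estimator, so large information means small approximate
#' standard errors.
#'
#' @param sens A `sensitivity_matrix` (time x observable x parameter
#'   array from [sensitivities()]), or a list of such arrays — one per
#'   experiment — which are summed (information is additive).
#' @param noise_cov Measurement-noise covariance at each sampling time:
#'   a scalar variance (same for every observable), a named-or-ordered
#'   vector of per-observable variances (diagonal covariance), or a full
#'   `n_obs x n_obs` matrix applied at every time.
#' @return An object of class `fim_result`: `fim`, `cov` (its inverse
#'   when numerically invertible), `criteria` (list with `D`, `E` and —
#'   when invertible — `A`), `condition_number`, `invertible`, `se`
#'   (approximate standard errors), `parameters`.
#' @export
compute_fim <- function(sens, noise_cov) {
  if (!is.list(sens)) sens <- list(sens)
  p_names <- dimnames(sens[[1]])[[3]]
  p <- length(p_names)
  fim <- matrix(0, p, p, dimnames = list(p_names, p_names))
  for (s in sens) {
    n_obs <- dim(s)[2]
    Sigma <- noise_cov_matrix(noise_cov, n_obs, dimnames(s)[[2]])
    Sigma_inv <- tryCatch(solve(Sigma), error = function(e) NULL)
    if (is.null(Sigma_inv)) stop("measurement covariance is singular")
    for (i in seq_len(dim(s)[1])) {
      Si <- matrix(s[i, , ], n_obs, p)
      if (anyNA(Si)) stop("non-finite sensitivities at time index ", i)
      fim <- fim + t(Si) %*% Sigma_inv %*% Si
    }
  }
  fim <- (fim + t(fim)) / 2  # enforce exact symmetry
  fim_result(fim)
}

# normalize the accepted noise_cov formats to a covariance matrix
noise_cov_matrix <- function(noise_cov, n_obs, obs_names) {
  if (is.matrix(noise_cov)) {
    stopifnot(nrow(noise_cov) == n_obs, ncol(noise_cov) == n_obs)
    return(noise_cov)
  }
  v <- as.numeric(noise_cov)
  if (length(v) == 1L) v <- rep(v, n_obs)
  if (!is.null(names(noise_cov)) && !is.null(obs_names)) {
    v <- as.numeric(noise_cov[obs_names])
  }
  if (length(v) != n_obs || anyNA(v) || any(v <= 0)) {
    stop("per-observable noise variances must be positive and match ",
         "the observables")
  }
  diag(v, n_obs, n_obs)
}

# package an information matrix with criteria and (pseudo)inverse
fim_result <- function(fim) {
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  invertible <- is.finite(cond) && cond < 1e12
  cov <- if (invertible) solve(fim) else NULL
  criteria <- list(D = det(fim), E = min(ev),
                   A = if (invertible) sum(diag(cov)) else NULL)
  structure(list(fim = fim, cov = cov, criteria = criteria,
                 condition_number = cond, invertible = invertible,
                 se = if (invertible) sqrt(diag(cov)) else NULL,
                 parameters = colnames(fim)),
            class = "fim_result")
}

#' @export
print.fim_result <- function(x, ...) {
  cat("<fim_result> parameters:", paste(x$parameters, collapse = ", "), "\n")
  cat("  D =", format(x$criteria$D, digits = 5),
      " E =", format(x$criteria$E, digits = 5),
      " A =", if (x$invertible) format(x$criteria$A, digits = 5)
              else "n/a (singular)", "\n")
  cat("  condition number:", format(x$condition_number, digits = 4), "\n")
  if (!is.null(x$se)) {
    cat("  approx. std. errors:\n")
    print(signif(x$se, 5))
  }
  invisible(x)
}

#' Scalar optimal-design criteria of the information matrix
#'
#' `D` is the determinant (to be maximized: minimizes the volume of the
#' joint confidence region), `E` the smallest eigenvalue (maximized:
#' shrinks the major axis), and `A` the trace of the inverse (minimized:
#' sum of approximate parameter variances). `A` requires an invertible
#' FIM — exactly the situation in which the Monte-Carlo Q-criterion
#' remains available.
#'
#' @param fim A square symmetric matrix or a `fim_result`.
#' @param which One of `"D"`, `"E"`, `"A"`.
#' @return The criterion value.
#' @export
fim_criterion <- function(fim, which = c("D", "E", "A")) {
  which <- match.arg(which)
  if (inherits(fim, "fim_result")) fim <- fim$fim
  stopifnot(is.matrix(fim), nrow(fim) == ncol(fim))
  ev <- eigen(fim, symmetric = TRUE, only.values = TRUE)$values
  switch(which,
         D = det(fim),
         E = min(ev),
         A = {
           cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
           if (!is.finite(cond) || cond >= 1e12) {
             stop("FIM non-invertible: A-criterion undefined ",
                  "(consider the Q-criterion)")
           }
           sum(diag(solve(fim)))
         })
}

#' Confidence ellipse for a parameter pair
#'
#' Builds the level-`level` confidence ellipse of the Gaussian
#' linearization for two parameters: the set of points whose squared
#' Mahalanobis distance from the center (under the 2x2 covariance
#' submatrix) is at most the chi-square quantile with 2 degrees of
#' freedom. For more than two parameters the marginal 2x2 submatrix of
#' the full covariance is used.
#'
#' @param cov Covariance: a `fim_result` (its inverse FIM is used) or a
#'   covariance matrix.
#' @param center Named parameter vector (at least the plotted pair).
#' @param pair Names or indices of the two parameters (default: first
#'   two).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return An object of class `confidence_ellipse` with `center`,
#'   `shape`, `level` and `axes` (half-axis lengths
#'   `sqrt(eigenvalue * qchisq(level, 2))` and directions).
#' @export
confidence_ellipse <- function(cov, center, pair = c(1L, 2L),
                               level = 0.95) {
  if (inherits(cov, "fim_result")) {
    if (!cov$invertible) stop("FIM non-invertible: no covariance bound")
    cov <- cov$cov
  }
  if (is.character(pair)) pair <- match(pair, colnames(cov))
  shape <- cov[pair, pair, drop = FALSE]
  ev <- eigen(shape, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("covariance submatrix not positive definite")
  center <- center[colnames(shape) %||% pair]
  q <- stats::qchisq(level, df = 2)
  structure(list(center = center, shape = shape, level = level,
                 axes = list(lengths = sqrt(ev$values * q),
                             directions = ev$vectors)),
            class = "confidence_ellipse")
}

#' Ellipse membership test
#'
#' @param ellipse A [confidence_ellipse()].
#' @param points A parameter pair, or a matrix with one point per row.
#' @return List with logical `inside` and numeric `mahalanobis2` (the
#'   squared Mahalanobis distance), one entry per point. A point is
#'   inside iff its squared distance is at most
#'   `qchisq(level, df = 2)`.
#' @export
ellipse_contains <- function(ellipse, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  d2 <- stats::mahalanobis(points, center = as.numeric(ellipse$center),
                           cov = ellipse$shape)
  q <- stats::qchisq(ellipse$level, df = 2)
  list(inside = d2 <= q, mahalanobis2 = unname(d2))
}

#' Sample the boundary polyline of a confidence ellipse
#'
#' @param ellipse A [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return Data frame with one boundary point per row, columns named
#'   after the parameter pair (for export/plotting).
#' @export
ellipse_boundary <- function(ellipse, n = 200L) {
  ang <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(ang), sin(ang))
  half <- ellipse$axes$directions %*% diag(ellipse$axes$lengths)
  pts <- t(half %*% circ + as.numeric(ellipse$center))
  colnames(pts) <- names(ellipse$center) %||% c("p1", "p2")
  as.data.frame(pts)
}
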