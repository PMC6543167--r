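test_that("measurement sets are validated on construction", {
  d <- design_vector(c(0.5, 1), x0 = c(S = 100, P = 0), t_end = 2)
  rec <- data.frame(experiment = "e1", time = c(0.5, 1),
                    observable = "S", value = c(50, 20), sigma = 0.4)
  expect_s3_class(measurement_set(rec, d), "measurement_set")
  bad <- rec; bad$sigma[2] <- 0
  expect_error(measurement_set(bad, d), "row\\(s\\): 2")
  expect_error(measurement_set(rec[, -5], d), "missing column")
  far <- rec; far$time[1] <- 5
  expect_error(measurement_set(far, d), "outside")
  expect_error(measurement_set(rec[0, ], d), "no records")
})

test_that("objective reduces to r^2/sigma^2 for a single record", {
  fx <- mm_fixture()
  d <- design_vector(0.463, x0 = fx$x0, t_end = 2)
  truth <- simulate_model(fx$model, fx$kin, d)$observables[1, "S"]
  rec <- data.frame(experiment = "e1", time = 0.463, observable = "S",
                    value = truth - 1.2, sigma = 0.5)
  ms <- measurement_set(rec, d)
  theta <- c(fx$kin, S0 = fx$x0[["S"]], P0 = fx$x0[["P"]])
  expect_equal(wls_objective(fx$model, theta, ms), 1.2^2 / 0.25,
               tolerance = 1e-6)
})

test_that("objective vanishes at the generating parameters and scales as 1/sigma^2", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  ms1 <- mm_base_data(d, sigma = 0.4)
  theta <- c(fx$kin, S0 = fx$x0[["S"]], P0 = fx$x0[["P"]])
  expect_lt(wls_objective(fx$model, theta, ms1), 1e-10)

  # perturb the data; doubling every variance halves J
  ms1$records$value <- ms1$records$value + c(0.3, -0.2, 0.1, 0.25)
  ms2 <- ms1
  ms2$records$sigma <- sqrt(2) * ms1$records$sigma
  J1 <- wls_objective(fx$model, theta, ms1)
  J2 <- wls_objective(fx$model, theta, ms2)
  expect_equal(J2, J1 / 2, tolerance = 1e-10)
})

test_that("Latin hypercube starts stratify every dimension", {
  bounds <- list(a = c(0, 10), b = c(-2, 2), c = c(1e-3, 1))
  pts <- lhs_starts(bounds, 10, seed = 99)
  expect_equal(dim(pts), c(10L, 3L))
  for (j in 1:3) {
    lo <- bounds[[j]][1]; w <- diff(bounds[[j]]) / 10
    bins <- floor((sort(pts[, j]) - lo) / w)
    expect_equal(bins, 0:9)
  }
  expect_equal(lhs_starts(bounds, 10, seed = 99), pts)
  expect_false(all(lhs_starts(bounds, 10, seed = 100) == pts))
  expect_true(all(lhs_starts(bounds, 1, seed = 1) >=
                    sapply(bounds, `[`, 1)))
  expect_error(lhs_starts(list(a = c(0, Inf)), 5, 1), "finite")
})

test_that("noise-free synthetic data returns the generating parameters", {
  fx <- mm_fixture()
  truth <- c(r_max = 85, K_S = 7.5)
  d <- design_vector(c(0.2, 0.5, 0.9, 1.4), x0 = c(S = 100, P = 0),
                     t_end = 2)
  ms <- generate_synthetic(fx$model, truth, d, noise_sd = 0,
                           sigma_report = 0.4)
  fit <- fit_parameters(fx$model, ms, mm_bounds2(), n_starts = 20, seed = 2)
  expect_lt(max(abs(fit$theta_hat - truth) / truth), 1e-4)
  expect_lt(fit$objective, 1e-10)
  expect_true(fit$converged)
})

test_that("the best objective over nested start sets is non-increasing", {
  fx <- mm_fixture()
  ms <- mm_table2_measurements()
  starts <- lhs_starts(mm_bounds4(), 12, seed = 8)
  fit_small <- fit_parameters(fx$model, ms, mm_bounds4(),
                              start = starts[1:4, ])
  fit_large <- fit_parameters(fx$model, ms, mm_bounds4(), start = starts)
  expect_lte(fit_large$objective, fit_small$objective + 1e-12)
  # and the cumulative best over the start sequence is monotone
  expect_true(all(diff(cummin(fit_large$per_start$objective)) <= 0))
})

test_that("fixed parameters are held exactly and do not hurt the fit", {
  fx <- mm_fixture()
  truth <- c(r_max = 85, K_S = 7.5)
  d <- design_vector(c(0.2, 0.5, 0.9, 1.4), x0 = c(S = 100, P = 0),
                     t_end = 2)
  ms <- generate_synthetic(fx$model, truth, d, noise_sd = 0,
                           sigma_report = 0.4)
  fit_free <- fit_parameters(fx$model, ms, mm_bounds2(), n_starts = 15,
                             seed = 3)
  fit_fixed <- fit_parameters(fx$model, ms,
                              bounds = mm_bounds2()["r_max"],
                              fixed = list(K_S = 7.5),
                              n_starts = 15, seed = 3)
  expect_false("K_S" %in% names(fit_fixed$theta_hat))
  expect_lt(fit_fixed$objective, fit_free$objective + 1e-8)
  expect_equal(fit_fixed$theta_hat[["r_max"]], 85, tolerance = 1e-5)
})

test_that("an under-determined fit warns", {
  fx <- mm_fixture()
  d <- design_vector(0.463, x0 = fx$x0, t_end = 2)
  rec <- data.frame(experiment = "e1", time = 0.463, observable = "S",
                    value = 51, sigma = 0.4)
  ms <- measurement_set(rec, d)
  w <- capture_warnings(
    try(fit_parameters(fx$model, ms, mm_bounds2(), n_starts = 2, seed = 1),
        silent = TRUE))
  expect_true(any(grepl("under-determined", w)))
})
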