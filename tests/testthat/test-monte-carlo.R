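test_that("a zero-noise ensemble reproduces the base fit in every replicate", {
  fx <- mm_fixture()
  base <- mm_base_data(mm_design_opt())
  ens <- run_ensemble(fx$model, base, noise_sigma = 0, n = 5, seed = 1,
                      fit_options = list(bounds = mm_bounds2(),
                                         theta0 = fx$kin))
  expect_equal(ens$n_converged, 5L)
  for (r in seq_len(nrow(ens$thetas))) {
    expect_equal(ens$thetas[r, ], ens$thetas[1, ], tolerance = 1e-12)
  }
  expect_equal(unname(ens$thetas[1, ]), unname(fx$kin), tolerance = 1e-6)
})

test_that("ensembles are bit-reproducible from the master seed", {
  fx <- mm_fixture()
  base <- mm_base_data(mm_design_opt())
  fo <- list(bounds = mm_bounds2(), theta0 = fx$kin)
  e1 <- run_ensemble(fx$model, base, noise_sigma = 0.4, n = 30, seed = 42,
                     fit_options = fo)
  e2 <- run_ensemble(fx$model, base, noise_sigma = 0.4, n = 30, seed = 42,
                     fit_options = fo)
  expect_identical(e1$thetas, e2$thetas)
  e3 <- run_ensemble(fx$model, base, noise_sigma = 0.4, n = 30, seed = 43,
                     fit_options = fo)
  expect_false(identical(e1$thetas, e3$thetas))
})

test_that("Q-criterion matches an independent sort-based implementation", {
  # explicit uniform grid: q0.9 - q0.1 = 0.7992 by direct interpolation
  x <- (1:1000) * 0.001 + 5
  expect_equal(q_criterion(x), bruteforce_q(x))
  expect_equal(q_criterion(x), 0.64, tolerance = 0.01)
  # all replicates identical
  expect_equal(q_criterion(matrix(2, 10, 3)), 0)
  withr::with_seed(31, {
    for (i in 1:10) {
      m <- matrix(rnorm(50 * 3, sd = 10^runif(1, -2, 2)), 50, 3)
      expect_equal(q_criterion(m), bruteforce_q(m), tolerance = 1e-12)
    }
  })
  expect_error(q_criterion(matrix(1, 1, 2)), "at least 2")
})

test_that("Q of standard-normal draws matches the closed form", {
  z9 <- qnorm(0.9)
  draws <- withr::with_seed(7, matrix(rnorm(1e6), ncol = 1))
  expect_equal(q_criterion(draws), (2 * z9)^2, tolerance = 0.01)
})

test_that("Q is insensitive to moving the largest replicate into the far tail", {
  draws <- withr::with_seed(19, matrix(rnorm(500 * 2), 500, 2))
  q0 <- q_criterion(draws)
  spiked <- draws
  spiked[which.max(spiked[, 1]), 1] <- 1e6
  expect_equal(q_criterion(spiked), q0, tolerance = 1e-12)
})

test_that("FIM-based Q sampling matches the closed form and scales correctly", {
  fim1 <- mbdoe:::fim_result(matrix(1, 1, 1, dimnames = list("a", "a")))
  q1 <- q_criterion_from_fim(fim1, c(a = 0), n = 1e6, seed = 3)
  expect_equal(q1, (2 * qnorm(0.9))^2, tolerance = 0.01)
  # quadrupling the information halves the spread: Q drops by 4 exactly
  fim4 <- mbdoe:::fim_result(matrix(4, 1, 1, dimnames = list("a", "a")))
  q4 <- q_criterion_from_fim(fim4, c(a = 0), n = 1e6, seed = 3)
  expect_equal(q4, q1 / 4, tolerance = 1e-12)
})

test_that("FIM-based and Monte-Carlo Q agree on the near-linear design", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  fim <- compute_fim(sensitivities(fx$model, fx$kin, d), 0.16)
  base <- mm_base_data(d)
  ens <- run_ensemble(fx$model, base, noise_sigma = 0.4, n = 500, seed = 2,
                      fit_options = list(bounds = mm_bounds2(),
                                         theta0 = fx$kin))
  q_mc <- q_criterion(ens)
  q_fim <- q_criterion_from_fim(fim, fx$kin, n = 5000, seed = 2)
  expect_equal(q_mc, q_fim, tolerance = 0.25)
})

test_that("coverage equals the nominal level for the FIM's own Gaussian", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  fim <- compute_fim(sensitivities(fx$model, fx$kin, d), 0.16)
  L <- chol(fim$cov)
  z <- withr::with_seed(4, matrix(rnorm(2e4 * 2), ncol = 2))
  draws <- sweep(z %*% L, 2, as.numeric(fx$kin), `+`)
  colnames(draws) <- names(fx$kin)
  ens <- structure(list(thetas = draws, base_theta = fx$kin),
                   class = "mc_ensemble")
  expect_equal(coverage_vs_fim(ens, fim, level = 0.95), 0.95,
               tolerance = 0.01)
})

test_that("coverage refuses a singular FIM and points to the Q-criterion", {
  sing <- mbdoe:::fim_result(matrix(c(1, 0, 0, 0), 2, 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  ens <- structure(list(thetas = matrix(0, 4, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                        base_theta = c(a = 0, b = 0)),
                   class = "mc_ensemble")
  expect_error(coverage_vs_fim(ens, sing), "Q-criterion")
})

test_that("subsampled Q values are normalized to mean one", {
  draws <- withr::with_seed(23, matrix(rnorm(200 * 2), 200, 2))
  qs <- robustness_subsample(draws, fraction = 0.8, repeats = 100, seed = 5)
  expect_equal(mean(qs), 1, tolerance = 1e-12)
  expect_equal(robustness_subsample(draws, fraction = 1, repeats = 10,
                                    seed = 5),
               rep(1, 10))
})

test_that("estimation error stays within the FIM-predicted standard errors", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  fim <- compute_fim(sensitivities(fx$model, fx$kin, d), 0.16)
  base <- mm_base_data(d)
  ens <- run_ensemble(fx$model, base, noise_sigma = 0.4, n = 100, seed = 9,
                      fit_options = list(bounds = mm_bounds2(),
                                         theta0 = fx$kin))
  med_err <- apply(abs(sweep(ens$thetas, 2, as.numeric(fx$kin))), 2,
                   stats::median)
  expect_true(all(med_err < 3 * fim$se))
})
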