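test_that("zero-noise synthesis reproduces the trajectory exactly", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  tr <- simulate_model(fx$model, fx$kin, d)
  ms <- generate_synthetic(fx$model, fx$kin, d, noise_sd = 0,
                           sigma_report = 0.4)
  expect_equal(ms$records$value, as.vector(tr$observables))
  expect_true(all(ms$records$sigma == 0.4))
})

test_that("synthetic noise has the requested standard deviation", {
  fx <- mm_fixture()
  d <- design_vector(0.463, x0 = fx$x0, t_end = 2)
  ms <- generate_synthetic(fx$model, fx$kin, d, noise_sd = 0.4,
                           n_replicates = 1e4, seed = 12)
  vals <- ms$records$value[ms$records$observable == "S"]
  truth <- simulate_model(fx$model, fx$kin, d)$observables[1, "S"]
  expect_equal(stats::sd(vals), 0.4, tolerance = 0.02)
  expect_equal(mean(vals), unname(truth), tolerance = 0.02)
  # same seed, same draws
  ms2 <- generate_synthetic(fx$model, fx$kin, d, noise_sd = 0.4,
                            n_replicates = 1e4, seed = 12)
  expect_identical(ms$records$value, ms2$records$value)
})

test_that("the printed benchmark table is regenerated by the fixture", {
  fx <- mm_fixture()
  tab <- mm_table2()
  d <- design_vector(sort(tab$t), x0 = fx$x0, t_end = 2)
  ms <- generate_synthetic(fx$model, fx$kin, d, noise_sd = 0,
                           sigma_report = 0.4)
  for (i in seq_len(nrow(tab))) {
    s_val <- ms$records$value[ms$records$observable == "S" &
                                abs(ms$records$time - tab$t[i]) < 1e-9]
    p_val <- ms$records$value[ms$records$observable == "P" &
                                abs(ms$records$time - tab$t[i]) < 1e-9]
    expect_lt(abs(s_val - tab$S[i]), 0.05)
    expect_lt(abs(p_val - tab$P[i]), 0.05)
  }
})

test_that("measurement CSV files round-trip losslessly", {
  fx <- mm_fixture()
  d <- mm_design_opt()
  ms <- generate_synthetic(fx$model, fx$kin, d, noise_sd = 0.4, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ms, path)
  back <- read_measurements(path, designs = ms$designs)
  expect_equal(back$records$value, ms$records$value)
  expect_equal(back$records$observable, ms$records$observable)
})

test_that("malformed measurement files are rejected with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("experiment,time,observable,value,sigma", path)
  expect_error(read_measurements(path), "no records")
  writeLines(c("experiment,time,observable,value,sigma",
               "e1,0.5,S,50,0.4",
               "e1,1.0,S,20,0"), path)
  expect_error(read_measurements(path), "line\\(s\\): 2")
  writeLines(c("experiment,time,value", "e1,0.5,50"), path)
  expect_error(read_measurements(path), "missing column")
})

test_that("run configurations load from YAML with a stable hash", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model: michaelis_menten",
               "parameters: {r_max: 120, K_S: 10}",
               "design:",
               "  sampling_times: [0.463, 1.070]",
               "  x0: {S: 100, P: 0.1}",
               "  t_end: 2",
               "noise: {var: 0.16}",
               "seed: 7"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$parameters$r_max, 120)
  expect_match(attr(cfg, "hash"), "^[0-9a-f]{32}$")
  d <- mbdoe:::config_design(cfg$design)
  expect_equal(d$sampling_times, c(0.463, 1.070))
  expect_equal(d$t_end, 2)
  expect_error(read_run_config(withr::local_tempfile(fileext = ".txt")),
               "unsupported")
})

test_that("the seven case-study conditions build valid designs", {
  tab <- table3_conditions()
  expect_equal(nrow(tab), 7L)
  d6 <- case_study_design(6, sampling_times = c(1, 2))
  expect_equal(unname(d6$x0["Thd"]), 50)
  expect_equal(unname(d6$u["Enz0"]), 0.230)
  expect_equal(unname(d6$u["temp"]), 60)
  pair <- case_study_design("5+7", sampling_times = c(1, 2))
  expect_named(pair, c("cond5", "cond7"))
  expect_equal(unname(pair$cond7$x0["Pi"]), 750)
})

test_that("CLI: synthesize-then-fit pipeline recovers a near-zero objective", {
  dir <- withr::local_tempdir()
  data_csv <- file.path(dir, "table2.csv")
  expect_equal(mbdoe_cli(c("synth", "--fixture", "table2",
                           "--out", data_csv)), 0L)
  expect_true(file.exists(data_csv))

  cfg <- file.path(dir, "run.yaml")
  writeLines(c("model: michaelis_menten",
               "parameters: {r_max: 120, K_S: 10}",
               "bounds:",
               "  r_max: [0.1, 1000]",
               "  K_S: [0.01, 1000]",
               "  S0: [50, 150]",
               "  P0: [0, 10]",
               "design:",
               "  sampling_times: [0.463, 0.750, 1.070, 1.500]",
               "  x0: {S: 100, P: 0.1}",
               "  t_end: 2",
               "noise: {var: 0.16}",
               "seed: 42"), cfg)
  fit_json <- file.path(dir, "fit.json")
  expect_equal(mbdoe_cli(c("fit", "--config", cfg, "--data", data_csv,
                           "--out", fit_json, "--starts", "40")), 0L)
  report <- jsonlite::read_json(fit_json)
  expect_lt(report$objective, 1e-4)
  expect_equal(report$theta_hat$r_max, 120, tolerance = 0.01)
})

test_that("CLI: Monte-Carlo runs are bit-identical for a fixed seed", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.yaml")
  writeLines(c("model: michaelis_menten",
               "parameters: {r_max: 120, K_S: 10}",
               "bounds:",
               "  r_max: [0.1, 1000]",
               "  K_S: [0.01, 1000]",
               "design:",
               "  sampling_times: [0.463, 1.070]",
               "  x0: {S: 100, P: 0.1}",
               "  t_end: 2",
               "noise: {var: 0.16}"), cfg)
  out1 <- file.path(dir, "mc1.csv"); out2 <- file.path(dir, "mc2.csv")
  expect_equal(mbdoe_cli(c("mc", "--config", cfg, "--n", "5",
                           "--seed", "1", "--out", out1)), 0L)
  expect_equal(mbdoe_cli(c("mc", "--config", cfg, "--n", "5",
                           "--seed", "1", "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))
  meta <- jsonlite::read_json(paste0(out1, ".json"))
  expect_equal(meta$n_converged, 5L)
})

test_that("CLI: degenerate A-optimal designs fail with a clear message", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.yaml")
  writeLines(c("model: phosphorolysis",
               "model_args: {observe: conversion}",
               "parameters: {K_M_S: 1.3, K_M_P: 5, k_catf: 300,",
               "  k_catr: 100, T_max: 50, T_width: 10}",
               "design:",
               "  sampling_times: [1.0]",
               "  x0: {Thd: 100, Pi: 750, Thy: 0, R1P: 0}",
               "  u: {Enz0: 0.117, temp: 50}",
               "  t_end: 4",
               "noise: {var: 9.0e-6}"), cfg)
  out <- file.path(dir, "design.csv")
  msgs <- capture.output(
    status <- mbdoe_cli(c("design", "--config", cfg, "--criterion", "A",
                          "--out", out)),
    type = "message")
  expect_equal(status, 1L)
  expect_match(paste(msgs, collapse = " "), "non-invertible")
})

test_that("CLI: unknown subcommands and malformed flags exit with status 2", {
  expect_equal(suppressMessages(mbdoe_cli(character(0))), 2L)
  expect_equal(suppressMessages(mbdoe_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(mbdoe_cli(c("fit", "--config"))), 2L)
})
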