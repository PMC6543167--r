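#' Generate synthetic measurements from a model
#'
#' Simulates the model under a design, samples the observables at the
#' given times and perturbs every value with iid zero-mean Gaussian
#' noise. Replicates share the sampling times but receive independent
#' noise, mirroring repeated experiments with duplicate samples per
#' time point.
#'
#' @param model A [kinetic_model].
#' @param params Named kinetic parameter vector.
#' @param design A [design_vector].
#' @param noise_sd Noise standard deviation: scalar or named per
#'   observable. `0` yields the exact trajectory values.
#' @param sampling_times Times to sample (default: the design's).
#' @param n_replicates Number of replicate series (default 1).
#' @param seed Integer seed.
#' @param experiment Experiment id prefix for the records.
#' @param sigma_report Value to store in the `sigma` column. Defaults
#'   to `noise_sd` when positive and to 1 (unit weights) when
#'   `noise_sd = 0`, since stored standard deviations must be positive.
#' @return A [measurement_set].
#' @export
generate_synthetic <- function(model, params, design, noise_sd,
                               sampling_times = design$sampling_times,
                               n_replicates = 1L, seed = 1L,
                               experiment = "exp1",
                               sigma_report = NULL) {
  sampling_times <- as.numeric(sampling_times)
  if (any(sampling_times < 0) || any(sampling_times > design$t_end)) {
    stop("sampling times outside the experiment horizon [0, ",
         design$t_end, "]")
  }
  traj <- simulate_model(model, params, design, eval_times = sampling_times)
  obs_names <- colnames(traj$observables)
  sd_vec <- if (!is.null(names(noise_sd))) {
    as.numeric(noise_sd[obs_names])
  } else {
    rep_len(as.numeric(noise_sd), length(obs_names))
  }
  if (anyNA(sd_vec) || any(sd_vec < 0)) {
    stop("noise_sd must be non-negative for every observable")
  }
  if (is.null(sigma_report)) {
    sigma_report <- ifelse(sd_vec > 0, sd_vec, 1)
  } else {
    sigma_report <- rep_len(as.numeric(sigma_report), length(obs_names))
  }

  one_rep <- data.frame(
    time = rep(sampling_times, length(obs_names)),
    observable = rep(obs_names, each = length(sampling_times)),
    value = as.vector(traj$observables),
    sigma = rep(sigma_report, each = length(sampling_times)),
    sd = rep(sd_vec, each = length(sampling_times)),
    stringsAsFactors = FALSE)
  records <- one_rep[rep(seq_len(nrow(one_rep)), n_replicates), ]
  records$experiment <- if (n_replicates == 1L) experiment
                        else rep(paste0(experiment, "_r", seq_len(n_replicates)),
                                 each = nrow(one_rep))
  rownames(records) <- NULL
  if (any(records$sd > 0)) {
    noise <- withr::with_seed(seed,
                              stats::rnorm(nrow(records), 0, records$sd))
    records$value <- records$value + noise
  }
  records$sd <- NULL
  designs <- stats::setNames(
    rep(list(design), length(unique(records$experiment))),
    unique(records$experiment))
  measurement_set(records[, c("experiment", "time", "observable",
                              "value", "sigma")],
                  designs)
}

#' The printed Michaelis-Menten benchmark table
#'
#' Substrate and product concentrations (g/L) on one batch trajectory,
#' sampled at the A-optimal two-point design `t_opt = {0.463, 1.070}` h
#' and at the naive design `t_bad = {0.750, 1.500}` h. Every row sums
#' to S + P = 100.1 g/L, so the whole table lies on a single trajectory
#' with `S0 + P0 = 100.1`. This table is the package's reference input:
#' the canonical parameter fixture is recovered from it by refitting
#' (see [mm_fixture_parameters()]).
#'
#' @return Data frame with columns `design` ("t_opt"/"t_bad"), `t`,
#'   `S`, `P`.
#' @export
mm_table2 <- function() {
  data.frame(
    design = c("t_opt", "t_opt", "t_bad", "t_bad"),
    t = c(0.463, 1.070, 0.750, 1.500),
    S = c(51.145, 3.940, 24.192, 0.033),
    P = c(48.955, 96.160, 75.908, 100.067),
    stringsAsFactors = FALSE)
}

#' Canonical Michaelis-Menten fixture parameters
#'
#' The parameter vector recovered once by fitting the Michaelis-Menten
#' model to all four rows of [mm_table2()] (weighted least squares, 50
#' Latin-hypercube starts; see `scripts/derive_mm_fixture.R` for the
#' derivation). The values are numerically indistinguishable from the
#' round numbers `r_max = 120`, `K_S = 10`, `S0 = 100`, `P0 = 0.1` up
#' to the table's three-decimal rounding.
#'
#' @param refit If `TRUE`, re-derive the fixture by refitting instead of
#'   returning the frozen constants.
#' @return Named vector `(r_max, K_S, S0, P0)`.
#' @export
mm_fixture_parameters <- function(refit = FALSE) {
  if (refit) {
    fit <- fit_parameters(
      mm_model(), mm_table2_measurements(),
      bounds = list(r_max = c(0.1, 1000), K_S = c(0.01, 1000),
                    S0 = c(50, 150), P0 = c(0, 10)),
      n_starts = 50, seed = 42)
    return(fit$theta_hat)
  }
  c(r_max = 119.995219820611, K_S = 9.998981533612,
    S0 = 99.998644906693, P0 = 0.101520544864)
}

#' Measurements built from the printed benchmark table
#'
#' @param rows Which rows of [mm_table2()] to include (default all 4).
#' @param sigma Reported measurement standard deviation per record
#'   (default 0.4, i.e. variance 0.16 — the noise model used throughout
#'   the Michaelis-Menten example).
#' @param t_end Experiment horizon (default 2 h).
#' @return A [measurement_set] with observables `S` and `P`.
#' @export
mm_table2_measurements <- function(rows = 1:4, sigma = 0.4, t_end = 2) {
  tab <- mm_table2()[rows, , drop = FALSE]
  ord <- order(tab$t)
  tab <- tab[ord, , drop = FALSE]
  records <- data.frame(
    experiment = "table2",
    time = rep(tab$t, 2L),
    observable = rep(c("S", "P"), each = nrow(tab)),
    value = c(tab$S, tab$P),
    sigma = sigma,
    stringsAsFactors = FALSE)
  design <- design_vector(tab$t, x0 = c(S = 100, P = 0.1), t_end = t_end)
  measurement_set(records, list(table2 = design))
}

#' Experimental conditions of the phosphorolysis case study
#'
#' The seven batch conditions varying thymidine, phosphate, enzyme load
#' and temperature.
#'
#' @return Data frame with columns `condition`, `Thd` (mM), `Pi` (mM),
#'   `enzyme` (mg/mL), `temp` (degrees C).
#' @export
table3_conditions <- function() {
  data.frame(
    condition = 1:7,
    Thd = c(100, 100, 100, 100, 100, 50, 50),
    Pi = c(250, 250, 250, 250, 750, 500, 750),
    enzyme = c(0.005, 0.117, 0.117, 0.117, 0.117, 0.230, 0.050),
    temp = c(40, 40, 50, 60, 50, 60, 40))
}

#' Build a case-study design from a condition row
#'
#' @param condition Condition number (1-7) of [table3_conditions()], or
#'   the string `"5+7"` for the pair of conditions the uncertainty
#'   analysis focuses on (returned as a list of two designs).
#' @param sampling_times Sampling times (h).
#' @param t_end Horizon (default: last sampling time).
#' @return A [design_vector], or a named list of two for `"5+7"`.
#' @export
case_study_design <- function(condition, sampling_times,
                              t_end = max(sampling_times)) {
  if (identical(condition, "5+7")) {
    return(list(cond5 = case_study_design(5, sampling_times, t_end),
                cond7 = case_study_design(7, sampling_times, t_end)))
  }
  tab <- table3_conditions()
  stopifnot(condition %in% tab$condition)
  row <- tab[tab$condition == condition, ]
  design_vector(sampling_times,
                x0 = c(Thd = row$Thd, Pi = row$Pi, Thy = 0, R1P = 0),
                u = c(Enz0 = row$enzyme, temp = row$temp),
                t_end = t_end)
}

#' Illustrative phosphorolysis parameters (synthetic)
#'
#' A plausible parameter set for exercising the case-study model in
#' simulations and tests. `K_M_S = 1.3` is the literature value the
#' estimation is regularized with (held fixed during fitting); the
#' remaining values are synthetic package defaults chosen to give
#' conversion dynamics on the hour scale under the Table-of-conditions
#' designs — they are not fitted to any experimental data.
#'
#' @return Named parameter vector for [phosphorolysis_model()].
#' @export
phosphorolysis_default_parameters <- function() {
  c(K_M_S = 1.3, K_M_P = 5, k_catf = 300, k_catr = 100,
    T_max = 50, T_width = 10)
}

#' Read / write measurement CSV files
#'
#' The on-disk format is a tidy UTF-8 CSV with header
#' `experiment,time,observable,value,sigma` and `.` as decimal mark.
#' Reading validates every row and reports offending line numbers;
#' writing round-trips losslessly.
#'
#' @param path File path.
#' @param designs Designs to attach to the records (as in
#'   [measurement_set()]); when omitted, a minimal single-experiment
#'   design spanning the observed times is constructed per experiment.
#' @return `read_measurements` returns a [measurement_set];
#'   `write_measurements` returns `path` invisibly.
#' @export
read_measurements <- function(path, designs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment", "time", "observable", "value", "sigma")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no records in ", path)
  for (col in c("time", "value", "sigma")) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))))
      stop("non-numeric '", col, "' at data line(s): ",
           paste(bad, collapse = ", "))
    }
  }
  bad_sigma <- which(df$sigma <= 0)
  if (length(bad_sigma)) {
    stop("sigma must be > 0; offending data line(s): ",
         paste(bad_sigma, collapse = ", "))
  }
  if (is.null(designs)) {
    ids <- unique(as.character(df$experiment))
    designs <- stats::setNames(lapply(ids, function(id) {
      times <- sort(unique(df$time[df$experiment == id]))
      # placeholder design: observed times, zero state (models needing a
      # real x0 must be given explicit designs)
      design_vector(times, x0 = numeric(0), t_end = max(times))
    }), ids)
  }
  measurement_set(df[required], designs)
}

#' @rdname read_measurements
#' @param set A [measurement_set].
#' @export
write_measurements <- function(set, path) {
  utils::write.csv(set$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration names the model, its parameter values (with an
#' optional `fixed` list), the design(s), the noise model, Monte-Carlo
#' and design-optimization settings, and a master seed. The returned
#' object carries the md5 hash of the file so every downstream report
#' can embed it.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `run_config` with a `hash` attribute.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
  if (is.null(cfg$model)) stop("config must name a 'model'")
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

# design_vector from a config 'design' block
config_design <- function(block) {
  design_vector(sampling_times = as.numeric(block$sampling_times),
                x0 = unlist(block$x0),
                u = if (!is.null(block$u)) unlist(block$u) else NULL,
                t_end = block$t_end %||% max(as.numeric(block$sampling_times)))
}

# append one JSON line to a run log
log_json_line <- function(path, event, ...) {
  line <- jsonlite::toJSON(c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                  event = event), list(...)),
                           auto_unbox = TRUE)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
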