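# Shared fixtures: the canonical Michaelis-Menten setup recovered from
# the printed benchmark table, and the two benchmark two-point designs.

mm_fixture <- function() {
  th <- mm_fixture_parameters()
  list(model = mm_model(),
       theta = th,
       kin = th[c("r_max", "K_S")],
       x0 = c(S = th[["S0"]], P = th[["P0"]]))
}

mm_design_opt <- function(x0 = mm_fixture()$x0)
  design_vector(c(0.463, 1.070), x0 = x0, t_end = 2)

mm_design_bad <- function(x0 = mm_fixture()$x0)
  design_vector(c(0.750, 1.500), x0 = x0, t_end = 2)

mm_bounds4 <- function()
  list(r_max = c(0.1, 1000), K_S = c(0.01, 1000),
       S0 = c(50, 150), P0 = c(0, 10))

mm_bounds2 <- function()
  list(r_max = c(0.1, 1000), K_S = c(0.01, 1000))

# noiseless measurements of the canonical fixture at a design
mm_base_data <- function(design, sigma = 0.4) {
  fx <- mm_fixture()
  generate_synthetic(fx$model, fx$kin, design, noise_sd = 0,
                     sigma_report = sigma)
}

# a Michaelis-Menten variant observing the substrate only (used to
# exercise rank-deficient information matrices)
mm_model_s_only <- function() {
  base <- mm_model()
  kinetic_model(
    name = "michaelis_menten_s",
    state_names = base$state_names,
    parameter_names = base$parameter_names,
    rhs = base$rhs,
    observation = function(state) state[1],
    obs_names = "S",
    obs_jac = function(state) matrix(c(1, 0), 1, 2),
    default_bounds = base$default_bounds,
    jac_state = base$jac_state,
    jac_params = base$jac_params)
}

# independent sort-based 10-90 percentile width criterion (oracle for
# q_criterion): linear interpolation between order statistics at
# position (n-1)p + 1, written from scratch
bruteforce_q <- function(thetas) {
  if (is.null(dim(thetas))) thetas <- matrix(thetas, ncol = 1)
  widths <- apply(thetas, 2, function(x) {
    x <- sort(x)
    n <- length(x)
    interp <- function(p) {
      h <- (n - 1) * p + 1
      lo <- floor(h)
      hi <- ceiling(h)
      x[lo] + (h - lo) * (x[hi] - x[lo])
    }
    interp(0.9) - interp(0.1)
  })
  sum(widths^2)
}
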