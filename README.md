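# mbdoe — model-based design of experiments for nonlinear ODE kinetics

`mbdoe` is an R toolbox for planning and analysing dynamic kinetic
experiments, aimed at bioprocess engineers and modellers who fit ODE
models to batch data. It answers two questions that decide whether a
handful of expensive samples will identify the model parameters:

* **How uncertain are my parameter estimates?** Via the classical
  Fisher-information (FIM) linearization *and* via Monte-Carlo
  re-estimation, which reveals the true, possibly banana-shaped
  confidence regions the FIM ellipse cannot represent.
* **When should I sample?** By optimizing the sampling times under the
  classical D-, E- and A-optimality criteria — or under a quantile-based
  **Q-criterion** that needs no matrix inversion and therefore survives
  the singular-FIM situations that break the classical criteria.

## The model and the statistics

Experiments follow the standard nonlinear state-space form

    dx/dt = f(x(t), u(t), θ),   ŷ(t_i) = g(x(t_i)) + η_i,   η_i ~ N(0, σ_i²) iid

Parameters are estimated by weighted least squares,
`J(θ) = Σ_exp (1/n_mes) Σ_k (y_k(θ) − ŷ_k)²/σ_k²`, minimized by
Latin-hypercube multistart Levenberg–Marquardt. Uncertainty is
approximated by `FIM = Σ S^T Σ_noise⁻¹ S` (S the output sensitivities;
`COV ⪰ FIM⁻¹` by Cramér–Rao) and measured exactly by re-fitting
noise-perturbed replicates. A Monte-Carlo ensemble `{θ̂_r}` is
summarized by the design criterion

    Q = Σ_i (Q_{θi,0.9} − Q_{θi,0.1})²,

the sum of squared 10–90 percentile widths (lower is better).

Two models ship built in: an irreversible Michaelis–Menten batch
conversion (`mm_model()`) and a reversible, temperature-dependent
nucleoside phosphorolysis under a quasi-steady-state approximation
(`phosphorolysis_model()`). New models plug in through
`kinetic_model()`.

## A worked example

The benchmark is a Michaelis–Menten batch with two measured states and
two samples. Fitting all four rows of the shipped concentration table
(`mm_table2()`) recovers the canonical parameter vector, and the
FIM-vs-Monte-Carlo comparison at the optimized design
`t_opt = {0.463, 1.070}` h runs in under a minute:

```r
library(mbdoe)

fit <- fit_parameters(mm_model(), mm_table2_measurements(),
                      bounds = list(r_max = c(0.1, 1000), K_S = c(0.01, 1000),
                                    S0 = c(50, 150), P0 = c(0, 10)),
                      n_starts = 50, seed = 42)
fit
#> <fit_result> J = 2.27687e-07 (converged)
#>      r_max        K_S         S0         P0
#> 119.995000   9.998980  99.998600   0.101521
#>    50 start(s); 50 finished
```

The objective `J ≈ 2e-07` says the four printed rows lie on a single
trajectory to within rounding; the estimates are numerically
`r_max = 120 g/L/h`, `K_S = 10 g/L`, `S0 + P0 = 100.1 g/L`.

```r
theta <- fit$theta_hat
kin <- theta[c("r_max", "K_S")]
design <- design_vector(c(0.463, 1.070),
                        x0 = c(S = theta[["S0"]], P = theta[["P0"]]), t_end = 2)

fim <- compute_fim(sensitivities(mm_model(), kin, design), noise_cov = 0.16)
base <- generate_synthetic(mm_model(), kin, design, noise_sd = 0,
                           sigma_report = 0.4)
ens <- run_ensemble(mm_model(), base, noise_sigma = 0.4, n = 5000, seed = 1,
                    fit_options = list(bounds = list(r_max = c(0.1, 1000),
                                                     K_S = c(0.01, 1000)),
                                       theta0 = kin))
coverage_vs_fim(ens, fim, level = 0.95)
#> [1] 0.953
q_criterion(ens)
#> [1] 21.25923
```

95.3% of the 5000 re-estimates fall inside the FIM's 95% ellipse: for
this near-linear design the linearization is a faithful picture of the
estimator distribution. Sampling-time optimization from the naive
design `{0.75, 1.5}` h converges in well under 30 iterations under
either criterion family:

```r
prob <- design_problem(mm_model(), kin, design, criterion = "A",
                       noise_sigma = 0.4)
optimize_design(prob, c(0.75, 1.5))$times
#> [1] 0.5033733 1.0903225
```

A thin command-line wrapper (`inst/cli/mbdoe`) exposes the same
workflow as `simulate`, `synth`, `fit`, `fim`, `mc` and `design`
subcommands driven by YAML/JSON configs; see `?mbdoe_cli`.

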