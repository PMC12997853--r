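# msplinesurv

Flexible Bayesian survival modelling with an M-spline hazard, and the
simulation machinery to assess its frequentist performance on realistic
oncology-trial scenarios.

The package is written for biostatisticians who fit flexible parametric
models to right-censored trial data — for example in health technology
assessment, where the restricted mean survival time (RMST) over trial
follow-up is a standard estimand — and who want to know how such a
Bayesian model behaves in repeated sampling: bias, interval coverage,
sensitivity to spline flexibility and smoothing priors, and how a fast
Laplace approximation compares with full MCMC.

## The model

The hazard is a weighted sum of `n` M-spline basis functions (cubic by
default, knots at quantiles of the uncensored event times):

    h(t | x) = eta0 * exp(beta' x) * sum_i p_i(x) b_i(t),    sum_i p_i = 1

Each `b_i` is nonnegative and integrates to 1, so the hazard is smooth and
positive, with `eta` acting as a pure scale. The weights are multinomial
logits `gamma_i = log(p_i / p_1)` with a hierarchical prior
`gamma_i = mu_i + sigma * eps_i`: the fixed means `mu_i` correspond to a
constant hazard, the smoothness parameter `sigma ~ Gamma(2, 1)` controls
departure from it, and the random effects `eps_i` follow a weighted
logistic random walk (or, optionally, an exchangeable Logistic(0,1)
model). Covariates act proportionally through `beta ~ N(0, 20)` on the
scale, and optionally non-proportionally through departures
`delta_is ~ N(0, tau_s)` on the logits, so the hazard ratio may vary over
time; `delta = 0` recovers proportional hazards exactly.

Inference is by adaptive Hamiltonian Monte Carlo (compiled log posterior
with analytic gradients; 4 chains x 2,000 iterations by default, with
split-Rhat, bulk-ESS and divergence diagnostics) or by a Laplace
approximation at the posterior mode for fast exploration.

Around the model sits a simulation laboratory: Royston-Parmar truth
models (natural cubic spline on the log cumulative hazard), four
time-varying hazard-ratio treatment scenarios, survival simulation by
cumulative-hazard inversion, exact estimand truths by quadrature with
Monte-Carlo cross-validation, a frequentist Royston-Parmar
maximum-likelihood comparator, and Morris-style performance measures
(bias, empirical SE, coverage, all with Monte-Carlo standard errors).

## Worked example

Simulate a 200-patient single-arm trial from the shipped
overall-survival-like truth model, fit the default Bayesian model, and
estimate the 5-year RMST:

```r
library(msplinesurv)

fx <- fixture_dgms()
trial <- simulate_trial(fx$os_like, scenario = NULL, n_per_arm = 200,
                        admin_censor_time = 5, seed = 42)
sum(trial$event)                      # 120 events of 200 patients

basis <- place_knots(trial$time[trial$event == 1], df = 10,
                     all_times = trial$time)
fit <- fit_mcmc(model_spec(basis), trial, seed = 42)
fit
#> Bayesian M-spline hazard fit (mcmc): 4000 draws, 11 parameters
#>   max split-Rhat 1.015, min bulk ESS 126, divergences 0/0/0/0

r5 <- rmst(fit, horizon = 5)
```

This run prints a posterior median 5-year RMST of 3.444 years with 95%
credible interval 3.214–3.651 (posterior SD 0.111). The generating
model's true value, from `true_estimands(fx$os_like, horizon = 5)`, is
3.586 years — within two posterior SDs for this particular simulated
dataset, as repeated-sampling calibration predicts. The diagnostics line
shows all four chains converged (max split-Rhat 1.015, well under the
1.05 flag) with no divergent transitions.

Two-arm data with a time-varying effect work the same way through
`simulate_trial(dgm, scenario, ...)`, a `model_spec()` with
`ph_covariates = "arm"` (and `nonph_covariates = "arm"` for the non-PH
model), and `rmstd()` / `hazard_ratio_curve()` for the treatment-effect
summaries.

## The analysis workflow

The `analysis/` directory holds the numbered study drivers, each a thin
script over package functions that prints what it finds and writes tidy
tables under `results/`:

| script | what it does |
|---|---|
| `01_truths.R` | quadrature truths for every fixture, cross-checked against 10^6-sample Monte-Carlo estimates |
| `02_single_arm_grid.R` | the 18-model grid (df x smoothness prior x coefficient model) on both fixtures |
| `03_calibration.R` | full-MCMC coverage for the default model and the Laplace-vs-MCMC comparison |
| `04_two_arm_scenarios.R` | PH and non-PH treatment-effect estimation under the four hazard-ratio scenarios |
| `05_frequentist_comparison.R` | Royston-Parmar maximum-likelihood comparators at df = 2..10 |

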