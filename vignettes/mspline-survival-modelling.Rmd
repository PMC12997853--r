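---
title: "Flexible Bayesian M-spline survival models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible Bayesian M-spline survival models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msplinesurv)
```

This vignette is the package's account of the statistical machinery it
implements: the Bayesian M-spline hazard model and its priors, the two
inference engines (adaptive Hamiltonian Monte Carlo and a Laplace
approximation), the Royston–Parmar data-generating machinery used to test
the model's frequentist properties, and the numerical and design choices
behind each. It states no empirical results; the numbers live in the
outputs of the `analysis/` scripts, the test suite, and
`scripts/acceptance.R`.

## The hazard model

The hazard of a right-censored survival outcome is modelled as a weighted
sum of $n$ M-spline basis functions $b_i(t)$,
$$ h(t) = \eta \sum_{i=1}^{n} p_i\, b_i(t), \qquad \sum_i p_i = 1,\; p_i \ge 0. $$
M-splines are nonnegative polynomial splines (cubic by default), each
normalised to integrate to 1 over the basis support $[L, U]$, so any convex
combination is a smooth positive function and $\eta$ is interpretable as a
scale: with the "constant-hazard" weights $p^{\mathrm{const}}$
(proportional to the knot spans) the hazard is exactly $\eta / (U - L)$.
The cumulative hazard uses the integrated basis (I-splines):
$H(t) = \eta \sum_i p_i I_i(t)$ with $I_i(t) = \int_L^t b_i(u)\,du$, so
survival $S(t) = e^{-H(t)}$, the likelihood
$\sum_{\mathrm{events}} \log h(t_j|x_j) - \sum_{\mathrm{all}} H(t_j|x_j)$,
and the restricted mean survival time
$\mathrm{RMST}(T) = \int_0^T S(t)\,dt$ are all available in closed form up
to quadrature of $S$.

Both basis families are evaluated through `splines::splineDesign()`:
an M-spline of degree $d$ is a B-spline of order $d+1$ rescaled by
$(d+1)/(\text{knot span})$, and its integral is a tail sum of B-splines of
order $d+2$ on a once-extended knot sequence. The unit tests hold both
identities to quadrature oracles at $10^{-8}$.

### Knots

By default the model uses $n = 10$ cubic basis functions. With degree $d$
and $m = n - d - 1$ internal knots, the internal knots sit at the
$i/(m+1)$ empirical quantiles (type 7) of the uncensored event times —
equally spaced quantile levels, the natural reading of "knots at quantiles
of the uncensored survival times". Boundary knots default to $L = 0$ and
$U = $ the largest observed time (event or censored), each repeated $d+1$
times. Tied quantiles (heavily discretised data) are collapsed to single
knots with a warning rather than kept at silent multiplicity, which would
degrade the basis conditioning; the basis then has fewer than `df`
functions. No hazard is defined beyond $U$: evaluation and RMST horizons
past the boundary are errors, not extrapolations.

### Priors and the smoothness hierarchy

Priors (all defaults weakly informative):

* $\log \eta \sim N(0, 20)$ — the second argument is a standard deviation
  throughout; a variance reading would make the prior essentially
  improper, and positivity of $\eta$ forces the log scale.
* The weights are parameterised by multinomial logits
  $\gamma_i = \log(p_i / p_1)$, $\gamma_1 = 0$, with hierarchy
  $\gamma_i = \mu_i + \sigma \epsilon_i$. The fixed means
  $\mu_i = \log(p^{\mathrm{const}}_i / p^{\mathrm{const}}_1)$ centre the
  prior on a constant hazard, and $\sigma$ measures departure from it.
* $\sigma \sim \mathrm{Gamma}(2, 1)$, shape–rate (so $\mathrm{Gamma}(2,20)$
  is the *tighter* prior, as the smoothness comparison requires).
* Random effects: the default is a weighted logistic random walk,
  $\epsilon_1 = 0$, $\epsilon_i \sim \mathrm{Logistic}(\epsilon_{i-1}, w_i)$,
  which shrinks *adjacent* basis coefficients together and hence the hazard
  toward local smoothness. The alternative `exchangeable` model uses iid
  $\epsilon_i \sim \mathrm{Logistic}(0, 1)$.
* PH effects: $\eta(x) = \eta_0 e^{\beta^\top x}$ with
  $\beta \sim N(0, 20)$. Non-PH (time-varying) effects shift the logits,
  $\gamma_i(x) = \mu_i + \delta_i^\top x + \sigma \epsilon_i$, with
  $\delta_{is} \sim N(0, \tau_s)$ and $\tau_s \sim \mathrm{Gamma}(2,1)$;
  $\delta_{is} = 0$ for all $i$ recovers proportional hazards exactly, a
  nesting the tests hold to $10^{-10}$ in the likelihood.

**Random-walk weights.** The weights $w_i$ should reflect the distance
between the regions of time that adjacent basis terms govern. We use the
spacing of the Greville abscissae — the mean of the $d$ interior knots of
each basis function's support — normalised to mean 1. Greville points are
strictly increasing for any valid knot sequence, whereas the more obvious
"support midpoint" rule degenerates to zero distance when two basis
supports coincide (which happens whenever there are few internal knots).
The rule is isolated in `rw_weights()` and is deliberately swappable.

**Prior calibration.** `prior_hazard_variability()` implements the
simulation-based summary used to interpret $\sigma$ priors: for each prior
draw it computes the ratio of the 90% to the 10% quantile of $h(t)$ over a
time grid — a scale-free measure of hazard variability — and reports the
distribution of that ratio. Tightening the $\sigma$ prior from
$\mathrm{Gamma}(2,1)$ to $\mathrm{Gamma}(2,20)$ shrinks this distribution
toward 1, which the property tests check stochastically.

## Inference

Both engines work on the unconstrained vector
$(\log\eta, \epsilon_{2..n}, \log\sigma, \beta, \delta, \log\tau)$ with
gamma-prior log-Jacobians for the log-transformed scales. The log posterior
and its analytic gradient are compiled (Rcpp); the R-level
`log_likelihood()` / `log_prior()` are an independent implementation of the
same densities, and the tests hold the two routes together at $10^{-8}$
alongside finite-difference gradient checks.

We kept the *centred* parameterisation deliberately. The tempting
alternative — sampling the logits $\gamma$ directly with $\sigma$ only in
the prior — has an unbounded posterior density: the change of variables
contributes $\sigma^{-(n-1)}$, so the density diverges as $\sigma \to 0$
with $\gamma \to \mu$, no MAP exists, and a Laplace approximation is
ill-defined. In the centred space the density is bounded and the mode
interior.

### Hamiltonian Monte Carlo

`fit_mcmc()` runs an adaptive HMC sampler: per chain, warmup adapts a
dual-averaged step size (target acceptance 0.9) in two phases with a
diagonal mass matrix estimated between them from warmup draws; sampling
uses the fixed adapted settings with the number of leapfrog steps drawn
uniformly up to `sim_length / stepsize` (default trajectory length 2 in
mass-standardised space, capped at 48 steps) to avoid resonances.
Divergences — non-finite Hamiltonians or energy errors above 1000 — are
counted per chain and reported; a low divergence count localized near the
$\sigma$–$\epsilon$ funnel is expected and does not invalidate estimates.
Defaults are 4 chains of 2,000 iterations, half warmup, retaining
4 × 1,000 draws. All randomness flows through R's RNG, so a single seed
makes fits byte-reproducible.

Convergence is summarised by rank-normalised split-$\hat R$ and bulk
effective sample size computed from Geyer initial-monotone-sequence
autocovariances. Reported flags: converged iff max $\hat R \le 1.05$;
adequate sampling iff min bulk ESS $\ge 400$ (against 4,000 retained
draws). Zero-variance chains are flagged degenerate rather than given
$\hat R = 1$; a single chain reports $\hat R$ as unavailable.

### Laplace approximation

`fit_laplace()` maximises the log posterior by BFGS with analytic
gradients (deterministically perturbed restarts on failure), takes the
covariance as the inverse of a central-difference Hessian of the gradient
at the mode, draws from the resulting Gaussian, and transforms to the
constrained scales. The reported point estimate is the posterior *median*
of the quantity of interest under these draws, matching the MCMC
convention. Because the mode in the centred space can sit at a larger
$\sigma$ than the bulk of the posterior, the approximation tends to
*overestimate* posterior spread — the conservative direction — while its
point estimates track the MCMC medians closely; the calibration analysis
(`analysis/03_calibration.R`) and the acceptance checks quantify both
effects on the shipped fixtures.

## The synthetic data engine

Truth models are Royston–Parmar flexible parametric models: a natural
cubic spline $s(\cdot)$ on log time models the log cumulative hazard,
$H(t) = e^{s(\log t)}$, $h(t) = H(t)\, s'(\log t)/t$. The basis is the
plain truncated-power natural cubic basis (linear tails beyond the
boundary knots); the orthogonalised basis some implementations use changes
only the coordinate system, not the model, and plain coordinates keep the
shipped coefficient vectors interpretable. Monotonicity of $H$ is
validated on a dense grid at construction — an invalid truth model is
rejected before any simulation happens.

Two baseline fixtures are shipped, emulating the qualitative shapes of
oncology trial hazards:

* `os_like` — 3 internal knots, gently varying unimodal hazard,
  overall-survival-like with 5-year survival near 0.44;
* `pfs_like` — 6 internal knots, a sharp hazard peak within the first year
  followed by decline, progression-free-survival-like with 5-year survival
  near 0.29.

Their coefficients are repository constants constructed by least-squares
spline fits to analytically specified target hazards (log-logistic-like
for `os_like`; a peaked gamma-kernel-plus-floor shape for `pfs_like`).
They are *synthetic*: they are not estimates from any trial dataset, and
every performance number in this repository refers to these fixtures'
own quadrature truths, not to published trial values. Externally estimated
parameter sets — e.g. models fitted to reconstructed trial data — drop in
through `dgm_from_config()` / `scenario_from_config()` (YAML).

Treatment effects are specified as a hazard ratio over time,
$h_1(t) = h_0(t)\,\mathrm{HR}(t)$, with four shipped scenarios: constant
$\mathrm{HR} = 0.7$; an immediate effect waning to 1 (logistic in time); a
delayed effect that then wanes (product of two logistics); and a
log-linear-in-time HR that crosses 1, tuned once by root-finding so the
true 5-year RMST difference is ~0. The closed forms and parameters are in
`hr_scenario()`; all are replaceable via config.

**Simulation by cumulative-hazard inversion.** Control-arm times solve
$H_0(t) = -\log U$ by bracketed root finding on $[10^{-8}, 200]$ years
with geometric bracket expansion and tolerance $10^{-10}$. The active-arm
cumulative hazard has no closed form, so
$H_1(t) = \int_0^t h_0(u)\mathrm{HR}(u)\,du$ is computed by 100-node
Gauss–Legendre quadrature applied piecewise between the baseline spline
knots, with a cubic substitution on the first piece to tame the power-law
behaviour of $h_0$ near zero; this reaches well below $10^{-8}$ absolute
error where naive single-panel quadrature stalls near $10^{-5}$.
Active-arm inversion initialises from a monotone grid interpolant of
$H_1$ and polishes with damped Newton steps on the exact $H_1$ (bracketed
root finding as fallback); draws landing beyond the administrative
censoring time are censored without inversion. Administrative censoring at
5 years (2 and 3 years for the early data cuts) truncates times and zeroes
the event indicator.

**Truth computation.** True RMST and RMSTD values come from adaptive
quadrature of the survival functions (relative tolerance $10^{-9}$). An
independent validation path estimates the same quantities as the mean of
$\min(T_i, T)$ over a large uncensored simulated sample with its
Monte-Carlo standard error; for such samples ($>10^5$) the inversion uses
a vectorised grid-plus-Newton scheme whose accuracy (~$10^{-9}$ relative)
is far inside the Monte-Carlo error. The acceptance checks run this
cross-validation at $10^7$ samples per fixture; the analysis scripts use
$10^6$ to stay desk-sized.

## The frequentist comparator

`fit_rp_mle()` is a maximum-likelihood Royston–Parmar fitter sharing the
natural-spline machinery with the data generator: baseline spline with
`df` parameters (df = 2 is exactly Weibull), treatment effects either
proportional, fully stratified (arm-specific increments on every baseline
coefficient, shared knots), or through a separate time-varying-effect
spline with its own `df` (1 = time-constant). Optimisation is BFGS from a
Weibull initialisation (via `survival::survreg`) with deterministic
restart perturbations — no RNG is consumed inside a fit, so simulation
streams are undisturbed. No monotonicity constraint is imposed, standard
practice for this model class: parameter values with a negative hazard at
an event time get zero likelihood, and final fits whose hazard dips
negative anywhere over follow-up are flagged. The covariance is the
inverse observed information. RMST inference offers the delta method
(numeric gradient through the covariance) and a nonparametric bootstrap of
individuals with refitting; the tests cross-check the fitter against
`flexsurv::flexsurvspline()` on shared data and the delta method against
the closed-form exponential answer.

## The simulation study

`sim_grid()` builds the model grid; the default single-arm Bayesian grid
crosses df ∈ {3, 6, 10}, $\sigma$ priors Gamma(2,1)/Gamma(2,5)/Gamma(2,20)
and the two coefficient models — 18 cells. `run_single_rep()` simulates
one dataset, fits one cell and returns one estimate record;
`run_grid()` loops cells × replicates with per-replicate seeds drawn once
from the master seed, so results are identical regardless of worker count
and any replicate is reproducible in isolation; per-cell record files make
runs resumable.

Performance measures follow standard simulation-study practice, each with
its Monte-Carlo standard error: bias (MCSE $= \widehat{SE}_{emp}/\sqrt{n}$),
relative bias in percent, empirical SE
(MCSE $= \widehat{SE}_{emp}/\sqrt{2(n-1)}$), mean posterior SD (or model
SE), and coverage of the 95% intervals
(MCSE $= \sqrt{c(1-c)/n}$). Replicates whose fit failed, or whose MCMC
run has max split-$\hat R > 1.05$, are excluded and counted separately —
convergence is reported as its own outcome, not mixed into the
performance rows. Relative bias is suppressed when the true value is
within 0.05 years of zero, where the ratio is numerically meaningless
(the crossing-curves scenario is the case in point).

### Problem sizes

The repository's runs are sized for a desk machine: trial sizes of 200
per arm match the emulated studies; the analysis scripts use 50–100
replicates per cell with Laplace fits for grid sweeps and 100 full-MCMC
replicates for the calibration of the default model; the acceptance
checks use 200 Laplace replicates for bias and 100 MCMC replicates for
coverage, with Monte-Carlo standard errors reported so the granularity of
each statement is visible. Truth validation uses $10^7$ draws in the
acceptance checks and $10^6$ in the scripts.

## What the synthetic study does and does not show

The generator reproduces the structural features that matter for the
model's frequentist assessment: realistic hazard shapes, administrative
censoring, two-arm designs with time-varying hazard ratios, and exactly
known truths. It does not emulate covariate-dependent censoring, accrual
patterns, discrete/tied event times, measurement error in reconstructed
curves, or any real trial's parameter values. Passing tests therefore
demonstrate internal statistical correctness (unbiasedness, calibration,
convergence behaviour) under these idealised but realistic conditions —
they are not a reanalysis of any published trial.

## Known limitations

* No extrapolation: hazards, survival and RMST are defined only up to the
  basis boundary; external evidence synthesis, cure fractions,
  relative-survival frameworks and effect-waning projections are out of
  scope.
* The Laplace engine inherits the centred-mode bias toward larger
  $\sigma$: interval estimates are conservative, and on data whose true
  hazard is nearly constant the overestimation of spread is substantial.
  It is an exploration tool; final inference should use MCMC.
* The exchangeable coefficient prior shrinks toward equal logits, not
  toward a constant hazard, and mixes more slowly; the random walk is the
  recommended default.
* The HMC sampler is a static-trajectory implementation with jittered
  step counts, not a tree-building no-U-turn sampler; it needs the
  adapted trajectory length to be roughly right, which the defaults
  achieve for the model sizes used here (up to ~22 parameters).
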