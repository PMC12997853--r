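## spec with df = 4 on [0, 5] (no internal knots): constant-hazard case has
## p = (1/4, 1/4, 1/4, 1/4), and eta equals the hazard level
flat_spec <- function(ph = character(0), nonph = character(0), ...) {
  model_spec(mspline_basis(degree = 3, lower = 0, upper = 5),
             ph_covariates = ph, nonph_covariates = nonph,
             priors = prior_spec(...))
}

theta_for <- function(spec, log_eta = 0, eps = NULL, log_sigma = 0,
                      beta = NULL, delta = NULL, log_tau = NULL) {
  ix <- msplinesurv:::par_layout(spec)
  th <- numeric(spec$n_par)
  th[ix$log_eta] <- log_eta
  if (!is.null(eps)) th[ix$eps] <- eps
  th[ix$log_sigma] <- log_sigma
  if (!is.null(beta)) th[ix$beta] <- beta
  if (!is.null(delta)) th[ix$delta] <- delta
  if (!is.null(log_tau)) th[ix$log_tau] <- log_tau
  th
}

## all log-prior terms except the spline-coefficient (eps) ones
manual_wo_eps <- function(th, spec) {
  ix <- msplinesurv:::par_layout(spec)
  dnorm(th[ix$log_eta], 0, 20, log = TRUE) +
    dgamma(exp(th[ix$log_sigma]), 2, 1, log = TRUE) + th[ix$log_sigma]
}

test_that("zero random effects recover the constant-hazard weights", {
  spec <- flat_spec()
  expect_equal(spline_coefs(theta_for(spec), spec),
               const_hazard_coefs(spec$basis))
  ## and for a basis with unequal spans
  spec_k <- model_spec(mspline_basis(knots = c(0.7, 3.9), lower = 0,
                                     upper = 5))
  expect_equal(spline_coefs(theta_for(spec_k), spec_k),
               const_hazard_coefs(spec_k$basis))

  ## softmax always sums to one, for any parameters
  set.seed(3)
  for (k in 1:5) {
    th <- rnorm(spec$n_par, 0, 2)
    expect_equal(sum(spline_coefs(th, spec)), 1, tolerance = 1e-12)
  }
})

test_that("zero delta makes the weights covariate-free (PH holds)", {
  spec <- flat_spec(ph = "arm", nonph = "arm")
  set.seed(4)
  th <- theta_for(spec, eps = rnorm(3), beta = 0.3, delta = rep(0, 3),
                  log_tau = 0.1)
  expect_equal(spline_coefs(th, spec, c(arm = 0)),
               spline_coefs(th, spec, c(arm = 1)))
})

test_that("hazard and cumulative hazard: exponential and PH special cases", {
  spec <- flat_spec()
  lambda <- 0.7
  ## with p = p_const the weighted basis sum is the constant 1/upper, so
  ## eta = lambda * upper gives h = lambda
  th <- theta_for(spec, log_eta = log(lambda * 5))
  tt <- seq(0, 5, by = 0.25)
  expect_equal(model_hazard(th, spec, NULL, tt), rep(lambda, length(tt)),
               tolerance = 1e-10)
  expect_equal(model_cumhaz(th, spec, NULL, tt), lambda * tt,
               tolerance = 1e-10)

  ## PH effect: beta = log 2 doubles hazard and cumulative hazard
  spec2 <- flat_spec(ph = "arm")
  set.seed(5)
  th2 <- theta_for(spec2, eps = rnorm(3), beta = log(2))
  tt <- c(0.5, 1, 2.7, 4.9)
  expect_equal(model_hazard(th2, spec2, c(arm = 1), tt),
               2 * model_hazard(th2, spec2, c(arm = 0), tt))
  expect_equal(model_cumhaz(th2, spec2, c(arm = 1), tt),
               2 * model_cumhaz(th2, spec2, c(arm = 0), tt))

  ## cumulative hazard equals the numerically integrated hazard
  H <- sapply(tt, function(ti)
    integrate(function(u) model_hazard(th2, spec2, c(arm = 0), u), 0, ti,
              rel.tol = 1e-10)$value)
  expect_equal(model_cumhaz(th2, spec2, c(arm = 0), tt), H,
               tolerance = 1e-7)

  expect_error(model_hazard(th, spec, NULL, 5.5), "extrapolation")
})

test_that("log likelihood matches closed forms and a brute-force oracle", {
  spec <- flat_spec()
  lambda <- 0.4
  th <- theta_for(spec, log_eta = log(lambda * 5))
  dat <- exp_surv_data(n = 60, rate = 0.5, censor = 5, seed = 2)
  ## exponential log likelihood, exactly
  expect_equal(log_likelihood(th, spec, dat),
               sum(dat$event) * log(lambda) - lambda * sum(dat$time),
               tolerance = 1e-10)
  ## all-censored data: minus the summed cumulative hazard
  cens <- data.frame(time = c(1, 2, 3), event = 0)
  expect_equal(log_likelihood(th, spec, cens), -lambda * 6,
               tolerance = 1e-10)

  ## brute force: hazard evaluated pointwise, cumulative hazard by
  ## adaptive quadrature, for a non-flat parameter vector
  set.seed(6)
  th2 <- theta_for(spec, log_eta = 0.2, eps = rnorm(3, 0, 0.5),
                   log_sigma = 0.3)
  brute <- sum(log(model_hazard(th2, spec, NULL,
                                dat$time[dat$event == 1]))) -
    sum(sapply(dat$time, function(ti)
      if (ti == 0) 0 else
        integrate(function(u) model_hazard(th2, spec, NULL, u), 0, ti,
                  rel.tol = 1e-10)$value))
  expect_equal(log_likelihood(th2, spec, dat), brute, tolerance = 1e-6)
})

test_that("log prior matches textbook densities", {
  spec <- flat_spec()
  ix <- msplinesurv:::par_layout(spec)
  set.seed(7)
  th <- theta_for(spec, log_eta = 0.3, eps = rnorm(3, 0, 0.8),
                  log_sigma = -0.2)
  eps <- c(0, th[ix$eps])
  manual <- dnorm(th[ix$log_eta], 0, 20, log = TRUE) +
    sum(dlogis(eps[-1], eps[-4], spec$w, log = TRUE)) +
    dgamma(exp(th[ix$log_sigma]), 2, 1, log = TRUE) + th[ix$log_sigma]
  expect_equal(log_prior(th, spec), manual, tolerance = 1e-12)

  ## at eps = 0 each random-walk logistic term is the density at its
  ## location, 1 / (4 w_i)
  th0 <- theta_for(spec, log_eta = 0.3, log_sigma = -0.2)
  expect_equal(log_prior(th0, spec) - manual_wo_eps(th0, spec),
               sum(log(1 / (4 * spec$w))), tolerance = 1e-12)

  ## sigma = 1 under Gamma(2, 1): gamma log density contributes exactly -1
  expect_equal(dgamma(1, 2, 1, log = TRUE), -1)

  ## exchangeable vs random walk differ only in the logistic terms
  spec_ex <- flat_spec(coef_model = "exchangeable")
  expect_equal(log_prior(th, spec_ex) - log_prior(th, spec),
               sum(dlogis(eps[-1], 0, 1, log = TRUE)) -
                 sum(dlogis(eps[-1], eps[-4], spec$w, log = TRUE)),
               tolerance = 1e-12)
})

test_that("non-PH likelihood with zero departures equals the PH likelihood", {
  fx <- fixture_dgms()
  dat <- simulate_trial(fx$os_like, fx$s1, n_per_arm = 40, seed = 8)
  basis <- place_knots(dat$time[dat$event == 1], df = 6,
                       all_times = dat$time)
  sp_ph <- model_spec(basis, ph_covariates = "arm")
  sp_np <- model_spec(basis, ph_covariates = "arm",
                      nonph_covariates = "arm")
  set.seed(9)
  th_ph <- rnorm(sp_ph$n_par, 0, 0.4)
  ix <- msplinesurv:::par_layout(sp_np)
  th_np <- numeric(sp_np$n_par)
  th_np[c(ix$log_eta, ix$eps, ix$log_sigma, ix$beta)] <- th_ph
  th_np[ix$delta] <- 0
  th_np[ix$log_tau] <- 0.3
  expect_equal(log_likelihood(th_np, sp_np, dat),
               log_likelihood(th_ph, sp_ph, dat), tolerance = 1e-10)
})

test_that("compiled log posterior equals the R likelihood plus prior, with
           matching gradients", {
  fx <- fixture_dgms()
  dat <- simulate_trial(fx$os_like, fx$s2, n_per_arm = 50, seed = 10)
  basis <- place_knots(dat$time[dat$event == 1], df = 6,
                       all_times = dat$time)
  for (cm in c("random_walk", "exchangeable")) {
    spec <- model_spec(basis, "arm", "arm", prior_spec(coef_model = cm))
    md <- msplinesurv:::make_model_data(spec, dat)
    set.seed(11)
    th <- rnorm(spec$n_par, 0, 0.4)
    res <- msplinesurv:::mspline_logpost_grad(md, th)
    expect_equal(res$lp, log_likelihood(th, spec, dat) + log_prior(th, spec),
                 tolerance = 1e-8)
    num <- sapply(seq_along(th), function(i) {
      h <- 1e-5
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (msplinesurv:::mspline_logpost_grad(md, tp)$lp -
         msplinesurv:::mspline_logpost_grad(md, tm)$lp) / (2 * h)
    })
    expect_equal(res$grad, num, tolerance = 1e-5)
  }
})

test_that("prior hazard variability: degenerate and ordered cases", {
  spec <- flat_spec()
  ## effectively zero smoothness: hazard is constant, ratio is 1
  tight <- model_spec(spec$basis,
                      priors = prior_spec(sigma_prior = c(2, 1e8)))
  r <- prior_hazard_variability(tight, n_draws = 50, seed = 1)
  expect_equal(r$ratios, rep(1, 50), tolerance = 1e-4)

  ## determinism under a fixed seed
  a <- prior_hazard_variability(spec, n_draws = 100, seed = 42)
  b <- prior_hazard_variability(spec, n_draws = 100, seed = 42)
  expect_identical(a, b)

  ## a stronger smoothness prior shrinks hazard variability
  set.seed(123)
  spec10 <- model_spec(place_knots(rexp(300, 0.4), df = 10, upper = 8),
                       priors = prior_spec(sigma_prior = c(2, 1)))
  spec10_tight <- model_spec(spec10$basis,
                             priors = prior_spec(sigma_prior = c(2, 20)))
  loose <- prior_hazard_variability(spec10, n_draws = 5000, seed = 7)
  tight <- prior_hazard_variability(spec10_tight, n_draws = 5000, seed = 7)
  expect_lt(tight$median, loose$median)
})
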