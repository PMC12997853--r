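## hand-built fits with known draws: df = 4 basis on [0, 5], so eps = 0
## gives a constant hazard eta / 5
fake_fit <- function(log_eta_draws, spec = NULL, extra = NULL) {
  if (is.null(spec))
    spec <- model_spec(mspline_basis(degree = 3, lower = 0, upper = 5))
  n <- length(log_eta_draws)
  draws <- matrix(0, n, spec$n_par,
                  dimnames = list(NULL, msplinesurv:::par_names(spec)))
  draws[, "log_eta"] <- log_eta_draws
  if (!is.null(extra)) for (nm in names(extra)) draws[, nm] <- extra[[nm]]
  attr(draws, "chain") <- rep(1L, n)
  structure(list(draws = draws, spec = spec, method = "fake"),
            class = "mspline_fit")
}

test_that("constant-hazard draws give exponential survival curves", {
  lambda <- 0.3
  fit <- fake_fit(rep(log(lambda * 5), 10))
  tt <- seq(0, 5, by = 0.5)
  sh <- survival_and_hazard(fit, NULL, tt)
  expect_equal(sh$survival$median, exp(-lambda * tt), tolerance = 1e-10)
  expect_equal(sh$hazard$median, rep(lambda, length(tt)), tolerance = 1e-10)
  expect_equal(sh$survival$median[tt == 0], 1)
})

test_that("per-draw survival is monotone nonincreasing with ordered CrIs", {
  set.seed(21)
  spec <- model_spec(mspline_basis(knots = c(1, 3), lower = 0, upper = 5))
  n <- 50
  draws <- matrix(rnorm(n * spec$n_par, 0, 0.5), n,
                  dimnames = list(NULL, msplinesurv:::par_names(spec)))
  attr(draws, "chain") <- rep(1L, n)
  fit <- structure(list(draws = draws, spec = spec, method = "fake"),
                   class = "mspline_fit")
  tt <- seq(0, 5, length.out = 60)
  S <- exp(-msplinesurv:::draw_cumhaz_matrix(fit, NULL, tt))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 1e-12))))
  sh <- survival_and_hazard(fit, NULL, tt)
  expect_true(all(sh$survival$lower <= sh$survival$median + 1e-12))
  expect_true(all(sh$survival$median <= sh$survival$upper + 1e-12))
  expect_true(all(sh$hazard$median >= 0))
})

test_that("RMST matches the exponential closed form and the quadrature
           oracle", {
  lambda <- 0.2
  fit <- fake_fit(rep(log(lambda * 5), 5))
  r <- rmst(fit, NULL, 5)
  expect_equal(r$median, (1 - exp(-1)) / 0.2, tolerance = 1e-4)
  expect_equal(rmst(fit, NULL, 0)$median, 0)
  expect_error(rmst(fit, NULL, 6), "extrapolation|boundary")

  ## random draws: Gauss-Legendre vs adaptive integration, draw by draw
  set.seed(22)
  fit2 <- fake_fit(rnorm(6, 0, 0.5),
                   extra = list(eps2 = rnorm(6, 0, 0.5),
                                eps3 = rnorm(6, 0, 0.5)))
  r2 <- rmst(fit2, NULL, 4.5)
  oracle <- sapply(seq_len(6), function(d) {
    th <- fit2$draws[d, ]
    integrate(function(u)
      exp(-model_cumhaz(th, fit2$spec, NULL, u)), 0, 4.5,
      rel.tol = 1e-10)$value
  })
  expect_equal(sort(r2$draws), sort(oracle), tolerance = 1e-6)

  ## RMST grows with the horizon and is bounded by it
  expect_lt(r$median, 5)
  expect_gt(rmst(fit, NULL, 5)$median, rmst(fit, NULL, 3)$median)
})

test_that("RMST difference: null, PH benefit, and arm-difference oracle", {
  spec <- model_spec(mspline_basis(degree = 3, lower = 0, upper = 5),
                     ph_covariates = "arm")
  ## beta = 0: no difference, every draw
  fit0 <- fake_fit(rnorm(8, 0, 0.3), spec = spec)
  d0 <- rmstd(fit0, c(arm = 1), c(arm = 0), 5)
  expect_equal(d0$draws, rep(0, 8))

  ## HR = 0.7 improves survival in every draw
  fit1 <- fake_fit(rnorm(8, 0, 0.3), spec = spec,
                   extra = list(beta_arm = rep(log(0.7), 8)))
  d1 <- rmstd(fit1, c(arm = 1), c(arm = 0), 5)
  expect_true(all(d1$draws > 0))

  ## equals the difference of separately computed arms
  ra <- rmst(fit1, c(arm = 1), 5)
  rc <- rmst(fit1, c(arm = 0), 5)
  expect_equal(d1$draws, ra$draws - rc$draws, tolerance = 1e-10)
  expect_true(d1$lower <= d1$median && d1$median <= d1$upper)
})

test_that("hazard-ratio curves are flat for PH models", {
  spec_np <- model_spec(mspline_basis(knots = 2, lower = 0, upper = 5),
                        ph_covariates = "arm", nonph_covariates = "arm")
  set.seed(23)
  nb <- spec_np$n_basis
  fit <- fake_fit(rnorm(10, 0, 0.3), spec = spec_np,
                  extra = c(list(beta_arm = rep(log(0.8), 10)),
                            setNames(lapply(2:nb, function(i) rnorm(10, 0, 0.4)),
                                     paste0("eps", 2:nb))))
  ## delta is zero in these draws, so the non-PH model reduces to PH
  tt <- seq(0.5, 4.5, by = 0.5)
  hr <- hazard_ratio_curve(fit, c(arm = 1), c(arm = 0), tt)
  expect_equal(hr$median, rep(0.8, length(tt)), tolerance = 1e-10)
  expect_equal(hr$lower, hr$upper, tolerance = 1e-10)
})

test_that("Gauss-Legendre nodes integrate polynomials exactly", {
  gl <- gauss_legendre(10)
  expect_equal(sum(gl$weights), 1, tolerance = 1e-12)
  ## degree-19 polynomial on [0, 1]
  expect_equal(sum(gl$weights * gl$nodes^19), 1 / 20, tolerance = 1e-12)
})
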