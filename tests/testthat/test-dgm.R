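test_that("a knot-free spline on log time is exactly Weibull", {
  shape <- 1.3; scale <- 3
  dgm <- weibull_dgm(shape, scale)
  tt <- c(0.1, 0.5, 1, 2.5, 5, 20)
  f <- rp_functions(dgm, tt)
  expect_equal(f$H, (tt / scale)^shape, tolerance = 1e-10)
  expect_equal(f$S, pweibull(tt, shape, scale, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(f$h, dweibull(tt, shape, scale) /
                 pweibull(tt, shape, scale, lower.tail = FALSE),
               tolerance = 1e-10)
  f0 <- rp_functions(dgm, 0)
  expect_equal(f0$S, 1)
  expect_equal(f0$H, 0)
})

test_that("hazard is the derivative of the cumulative hazard", {
  dgm <- fixture_dgms()$pfs_like
  tt <- seq(0.1, 6, length.out = 40)
  h <- 1e-6
  fd <- (rp_functions(dgm, tt + h)$H - rp_functions(dgm, tt - h)$H) / (2 * h)
  expect_equal(rp_functions(dgm, tt)$h, fd, tolerance = 1e-5)

  ## survival nonincreasing on a dense grid from 1
  S <- rp_functions(dgm, seq(0, 10, length.out = 500))$S
  expect_equal(S[1], 1)
  expect_true(all(diff(S) <= 1e-12))
})

test_that("a nonmonotone log-cumulative-hazard spline is rejected", {
  expect_error(rp_dgm(log(c(0.1, 1, 10)), c(0, 1, 5)), "nondecreasing")
})

test_that("cumulative-hazard inversion reproduces the target distribution", {
  dgm <- weibull_dgm(1.3, 3)
  n <- 50000
  tt <- simulate_control(dgm, n, seed = 41)
  ## Kolmogorov distance to the closed-form CDF
  ks <- max(abs(ecdf(tt)(sort(tt)) - pweibull(sort(tt), 1.3, 3)))
  expect_lt(ks, 0.01)
  ## same seed, same times
  expect_identical(tt[1:100], simulate_control(dgm, 100, seed = 41))
  ## event fraction below a cutoff matches 1 - S(c)
  c0 <- 2.5
  p <- 1 - rp_functions(dgm, c0)$S
  expect_lt(abs(mean(tt <= c0) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("plugging simulated times back through H gives uniform draws", {
  dgm <- fixture_dgms()$os_like
  n <- 20000
  tt <- simulate_control(dgm, n, seed = 42)
  u <- exp(-rp_functions(dgm, tt)$H)
  ks <- suppressWarnings(ks.test(u, "punif"))$statistic
  expect_lt(unname(ks), 0.015)
})

test_that("active-arm cumulative hazard: constant factors and quadrature
           oracle", {
  fx <- fixture_dgms()
  dgm <- fx$os_like
  tt <- c(0.5, 1, 2, 3.7, 5)
  H0 <- rp_functions(dgm, tt)$H
  s_unit <- hr_scenario("constant", list(hr = 1))
  s_07 <- hr_scenario("constant", list(hr = 0.7))
  expect_equal(active_cumhaz(dgm, s_unit, tt), H0, tolerance = 1e-8)
  expect_equal(active_cumhaz(dgm, s_07, tt), 0.7 * H0, tolerance = 1e-8)
  expect_equal(active_cumhaz(dgm, s_07, 0), 0)

  ## arbitrary smooth scenario vs adaptive quadrature
  oracle <- sapply(tt, function(ti)
    integrate(function(u) rp_functions(dgm, u)$h * fx$s2$hr(u), 0, ti,
              rel.tol = 1e-10)$value)
  expect_equal(active_cumhaz(dgm, fx$s2, tt), oracle, tolerance = 1e-6)
})

test_that("trial simulation censors administratively and respects PH", {
  fx <- fixture_dgms()
  d1 <- simulate_trial(fx$os_like, NULL, n_per_arm = 300,
                       admin_censor_time = 5, seed = 43)
  expect_equal(names(d1), c("time", "event"))
  expect_true(all(d1$time <= 5))
  expect_true(all(d1$event[d1$time == 5] == 0))
  p_event <- 1 - rp_functions(fx$os_like, 5)$S
  expect_lt(abs(mean(d1$event) - p_event),
            3 * sqrt(p_event * (1 - p_event) / 300))

  ## constant HR on a Weibull control: active arm is Weibull with
  ## rescaled scale parameter
  wb <- weibull_dgm(1.3, 3)
  d2 <- simulate_trial(wb, fx$s1, n_per_arm = 4000,
                       admin_censor_time = 1e6, seed = 44)
  act <- d2$time[d2$arm == 1]
  scale_act <- 3 / 0.7^(1 / 1.3)
  ks <- max(abs(ecdf(act)(sort(act)) - pweibull(sort(act), 1.3, scale_act)))
  expect_lt(ks, 0.03)

  ## degenerate censoring time censors everyone
  d3 <- simulate_trial(fx$os_like, NULL, n_per_arm = 50,
                       admin_censor_time = 1e-4, seed = 45)
  expect_true(all(d3$event == 0))
  expect_true(all(d3$time == 1e-4))
})

test_that("true estimands: closed forms and internal consistency", {
  ## exponential control: RMST closed form
  lam <- 0.5
  expdgm <- rp_dgm(log(c(0.01, 50)), c(log(lam), 1))
  te <- true_estimands(expdgm, horizon = 5)
  expect_equal(te$rmst_control, (1 - exp(-lam * 5)) / lam, tolerance = 1e-6)

  ## unit hazard ratio: exactly zero RMSTD
  s_unit <- hr_scenario("constant", list(hr = 1))
  te2 <- true_estimands(fixture_dgms()$os_like, s_unit, horizon = 5)
  expect_lt(abs(te2$rmstd), 1e-6)
})

test_that("shipped fixtures are valid and have their designed shapes", {
  fx <- fixture_dgms()
  expect_length(fx$os_like$knots, 5)    # 3 internal knots
  expect_length(fx$pfs_like$knots, 8)   # 6 internal knots

  ## os-like: 5-year survival in the 0.4-0.5 band, gently varying hazard
  S5 <- rp_functions(fx$os_like, 5)$S
  expect_gt(S5, 0.4); expect_lt(S5, 0.5)
  h_os <- rp_functions(fx$os_like, seq(0.1, 5, by = 0.05))$h
  expect_lt(max(h_os) / min(h_os), 15)

  ## pfs-like: sharp early peak then decline
  tgrid <- seq(0.05, 5, by = 0.05)
  h_pfs <- rp_functions(fx$pfs_like, tgrid)$h
  tpeak <- tgrid[which.max(h_pfs)]
  expect_lt(tpeak, 1)
  expect_lt(h_pfs[length(h_pfs)], max(h_pfs) / 2)

  ## scenario 1 is constant at 0.7
  expect_equal(fx$s1$hr(c(0.1, 1, 4.9)), rep(0.7, 3))
  ## scenario 4 crosses 1 and has near-zero 5-year RMSTD
  expect_lt(fx$s4$hr(0.5), 1)
  expect_gt(fx$s4$hr(4.5), 1)
  te4 <- true_estimands(fx$os_like, fx$s4, horizon = 5)
  expect_lt(abs(te4$rmstd), 0.05)
})

test_that("DGMs and scenarios round-trip through YAML configs", {
  fx <- fixture_dgms()
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "dgm.yaml")
  yaml::write_yaml(list(knots = fx$os_like$knots, coefs = fx$os_like$coefs,
                        label = "external"), f1, precision = 12)
  d <- dgm_from_config(f1)
  expect_equal(d$coefs, fx$os_like$coefs)
  expect_equal(rp_functions(d, 2.5)$S, rp_functions(fx$os_like, 2.5)$S)

  f2 <- file.path(dir, "scen.yaml")
  yaml::write_yaml(list(form = "loglinear",
                        pars = list(c0 = -0.6, c1 = 0.25), id = 9), f2)
  s <- scenario_from_config(f2)
  expect_equal(s$hr(2), exp(-0.6 + 0.5))
})
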