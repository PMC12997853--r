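test_that("performance measures match their defining formulas", {
  rec <- data.frame(cell = 1, rep = 1:3, status = "ok",
                    point = c(1, 2, 3), sd = c(0.5, 0.5, 0.5),
                    lower = c(0, 0, 1.5), upper = c(3, 1, 3),
                    max_rhat = NA, min_ess = NA, divergences = NA,
                    converged = TRUE)
  p <- performance(rec, truth = 2)
  expect_equal(p$bias, 0)
  expect_equal(p$emp_se, 1)
  expect_equal(p$coverage, 2 / 3)
  expect_equal(p$coverage_mcse, sqrt((2 / 3) * (1 / 3) / 3))
  expect_equal(p$bias_mcse, 1 / sqrt(3))
  expect_equal(p$rel_bias_pct, 0)

  ## relative bias suppressed near a zero truth
  p0 <- performance(rec, truth = 0.01)
  expect_true(is.na(p0$rel_bias_pct))
})

test_that("performance measures are calibrated on simulated records", {
  set.seed(71)
  n <- 10000; th <- 2; s <- 0.3
  est <- rnorm(n, th, s)
  rec <- data.frame(cell = 1, rep = 1:n, status = "ok", point = est, sd = s,
                    lower = est - 1.96 * s, upper = est + 1.96 * s,
                    max_rhat = NA, min_ess = NA, divergences = NA,
                    converged = TRUE)
  p <- performance(rec, truth = th)
  expect_lt(abs(p$bias), 3 * s / sqrt(n))
  expect_lt(abs(p$coverage - 0.95), 3 * p$coverage_mcse + 1e-9)
  expect_equal(p$emp_se, s, tolerance = 0.05)
})

test_that("non-converged and failed replicates are excluded and counted", {
  rec <- data.frame(cell = 1, rep = 1:4, status = c("ok", "ok", "ok",
                                                    "error: boom"),
                    point = c(1, 2, 3, NA), sd = 1,
                    lower = c(0, 0, 0, NA), upper = c(4, 4, 4, NA),
                    max_rhat = c(1, 1, 1.2, NA), min_ess = 500,
                    divergences = 0,
                    converged = c(TRUE, TRUE, FALSE, TRUE))
  p <- performance(rec, truth = 2)
  expect_equal(p$n_reps, 2)
  expect_equal(p$n_failed, 1)
  expect_equal(p$n_nonconverged, 1)
  expect_equal(p$mean_est, 1.5)
})

test_that("the default Bayesian single-arm grid has exactly 18 cells", {
  g <- sim_grid()
  expect_equal(nrow(g), 18)
  expect_setequal(unique(g$df), c(3, 6, 10))
  expect_setequal(unique(g$sigma_rate), c(1, 5, 20))
  expect_setequal(unique(g$coef), c("random_walk", "exchangeable"))
})

test_that("replicates are deterministic given the master seed", {
  g <- sim_grid(df = 6, sigma_prior = list(c(2, 1)),
                coef_model = "random_walk", method = "laplace")
  r1 <- run_single_rep(g, cell = 1, rep = 3, master_seed = 99)
  r2 <- run_single_rep(g, cell = 1, rep = 3, master_seed = 99)
  expect_identical(r1, r2)
  r3 <- run_single_rep(g, cell = 1, rep = 3, master_seed = 100)
  expect_false(identical(r1$point, r3$point))
  expect_equal(r1$status, "ok")
})

test_that("single-arm cells estimate RMST; two-arm cells estimate RMSTD", {
  fx <- fixture_dgms()
  truth1 <- true_estimands(fx$os_like, horizon = 5)$rmst_control
  g1 <- sim_grid(df = 10, sigma_prior = list(c(2, 1)),
                 coef_model = "random_walk", method = "laplace")
  r1 <- run_single_rep(g1, 1, 1, master_seed = 7)
  expect_lt(abs(r1$point - truth1), 1)     # an RMST-scale value

  g2 <- sim_grid(scenario = "s1", df = 6, sigma_prior = list(c(2, 1)),
                 coef_model = "random_walk", model_type = "bayes_ph",
                 method = "laplace")
  r2 <- run_single_rep(g2, 1, 1, master_seed = 7)
  expect_lt(abs(r2$point), 1.5)            # an RMSTD-scale value
})

test_that("failed fits are recorded, not fatal", {
  ## no events at a tiny censoring time: the Bayesian fit must refuse
  g <- sim_grid(df = 6, sigma_prior = list(c(2, 1)),
                coef_model = "random_walk", method = "laplace",
                censor_time = 1e-4)
  r <- run_single_rep(g, 1, 1, master_seed = 8)
  expect_match(r$status, "error")
  expect_true(is.na(r$point))
})

test_that("grids aggregate, resume, and produce identical resumed results", {
  g <- sim_grid(df = c(6, 10), sigma_prior = list(c(2, 1)),
                coef_model = "random_walk", method = "laplace")
  expect_equal(nrow(g), 2)
  dir <- withr::local_tempdir()
  res1 <- run_grid(g, reps = 3, master_seed = 5, out_dir = dir)
  expect_equal(nrow(res1$performance), 2)
  expect_true(all(res1$performance$n_reps <= 3))
  ## resumed run reuses the stored records and reproduces the table
  res2 <- run_grid(g, reps = 3, master_seed = 5, out_dir = dir)
  expect_equal(res1$performance, res2$performance)
  ## fresh run without the cache also agrees
  res3 <- run_grid(g, reps = 3, master_seed = 5)
  expect_equal(res1$performance$mean_est, res3$performance$mean_est)

  f <- report_tables(res1, file.path(dir, "report"))
  tab <- read.csv(file.path(dir, "report", "performance.csv"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_est, res1$performance$mean_est)
})

test_that("survival data round-trip through CSV", {
  fx <- fixture_dgms()
  dat <- simulate_trial(fx$os_like, fx$s1, n_per_arm = 20, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_surv_data(dat, f)
  back <- read_surv_data(f)
  expect_equal(back, dat)
  expect_error(read_surv_data({
    bad <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(time = -1, event = 2), bad, row.names = FALSE)
    bad
  }))
})
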