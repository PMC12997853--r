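## Simulation-study orchestration: model grids, single-replicate execution,
## Morris-style performance measures with Monte-Carlo standard errors, and
## tidy report tables.

#' Build a simulation grid
#'
#' Each row of the returned data frame is one model/inference cell evaluated
#' on the same stream of simulated datasets. The default Bayesian single-arm
#' grid crosses df in {3, 6, 10}, sigma priors Gamma(2,1) / Gamma(2,5) /
#' Gamma(2,20) and the random-walk vs exchangeable coefficient models: 18
#' cells.
#'
#' @param dgm fixture name (`"os_like"`, `"pfs_like"`) or an [rp_dgm()].
#' @param scenario NULL (single arm), a fixture name (`"s1"`..`"s4"`) or an
#'   [hr_scenario()].
#' @param model_type `"bayes_ph"` (single-arm or PH treatment effect),
#'   `"bayes_nonph"`, `"rp_ph"`, `"rp_stratified"` or `"rp_tve"`.
#' @param df M-spline (or baseline spline) degrees of freedom, vectorised.
#' @param sigma_prior list of `(shape, rate)` pairs for the smoothness prior.
#' @param coef_model character vector of spline-coefficient models.
#' @param tau_prior list of `(shape, rate)` pairs for the non-PH smoothness
#'   prior (non-PH models only).
#' @param tve_df time-varying-effect df for `"rp_tve"`.
#' @param method `"mcmc"` or `"laplace"` (Bayesian cells).
#' @param n_per_arm,censor_time,horizon trial size per arm, administrative
#'   censoring time, and estimand horizon (years).
#' @return data frame of cells with class `sim_grid`.
#' @export
sim_grid <- function(dgm = "os_like", scenario = NULL,
                     model_type = "bayes_ph",
                     df = c(3, 6, 10),
                     sigma_prior = list(c(2, 1), c(2, 5), c(2, 20)),
                     coef_model = c("random_walk", "exchangeable"),
                     tau_prior = list(c(2, 1)),
                     tve_df = 0,
                     method = "mcmc",
                     n_per_arm = 200, censor_time = 5, horizon = 5) {
  bayes <- grepl("^bayes", model_type)
  g <- expand.grid(df = df,
                   sigma = if (bayes) seq_along(sigma_prior) else 1,
                   coef = if (bayes) coef_model else "none",
                   tau = if (model_type == "bayes_nonph")
                     seq_along(tau_prior) else 1,
                   tve_df = tve_df,
                   method = if (bayes) method else "mle",
                   stringsAsFactors = FALSE)
  g$model_type <- model_type
  g$sigma_shape <- vapply(g$sigma, function(i) sigma_prior[[i]][1], 1)
  g$sigma_rate <- vapply(g$sigma, function(i) sigma_prior[[i]][2], 1)
  g$tau_shape <- vapply(g$tau, function(i) tau_prior[[i]][1], 1)
  g$tau_rate <- vapply(g$tau, function(i) tau_prior[[i]][2], 1)
  g$sigma <- g$tau <- NULL
  g$cell <- seq_len(nrow(g))
  attr(g, "dgm") <- dgm
  attr(g, "scenario") <- scenario
  attr(g, "n_per_arm") <- n_per_arm
  attr(g, "censor_time") <- censor_time
  attr(g, "horizon") <- horizon
  class(g) <- c("sim_grid", class(g))
  g
}

resolve_dgm <- function(x) {
  if (inherits(x, "rp_dgm")) return(x)
  fixture_dgms()[[x]]
}

resolve_scenario <- function(x) {
  if (is.null(x) || inherits(x, "hr_scenario")) return(x)
  fixture_dgms()[[x]]
}

## deterministic per-replicate seeds from the master seed
rep_seeds <- function(master_seed, reps) {
  set.seed(master_seed)
  sample.int(2^31 - 2, reps)
}

#' Run one simulation replicate for one grid cell
#'
#' Simulates a dataset (shared across cells through the per-replicate seed),
#' fits the cell's model and computes the estimand: RMST at the horizon for
#' single-arm settings, RMSTD for two-arm settings. Fit failures are caught
#' and reported as a record with `status != "ok"`.
#'
#' @param grid a [sim_grid()].
#' @param cell cell index (row of `grid`).
#' @param rep replicate index.
#' @param master_seed master seed; the replicate seed is drawn from it.
#' @param iterations,chains MCMC settings for `method = "mcmc"`.
#' @param laplace_draws draws for `method = "laplace"`.
#' @return one-row data frame: `cell`, `rep`, `status`, `point`, `sd`,
#'   `lower`, `upper`, `max_rhat`, `min_ess`, `divergences`, `converged`.
#' @export
run_single_rep <- function(grid, cell, rep, master_seed = 1,
                           iterations = 2000, chains = 4,
                           laplace_draws = 4000) {
  cfg <- grid[grid$cell == cell, ]
  stopifnot(nrow(cfg) == 1)
  dgm <- resolve_dgm(attr(grid, "dgm"))
  scenario <- resolve_scenario(attr(grid, "scenario"))
  horizon <- attr(grid, "horizon")
  seed <- rep_seeds(master_seed, max(rep, 1))[rep]
  dat <- simulate_trial(dgm, scenario, attr(grid, "n_per_arm"),
                        attr(grid, "censor_time"), seed = seed)
  rec <- data.frame(cell = cell, rep = rep, status = "ok",
                    point = NA_real_, sd = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    max_rhat = NA_real_, min_ess = NA_real_,
                    divergences = NA_real_, converged = TRUE,
                    stringsAsFactors = FALSE)
  res <- try({
    if (grepl("^bayes", cfg$model_type)) {
      basis <- place_knots(dat$time[dat$event == 1], df = cfg$df,
                           all_times = dat$time)
      pr <- prior_spec(sigma_prior = c(cfg$sigma_shape, cfg$sigma_rate),
                       coef_model = cfg$coef,
                       tau_prior = c(cfg$tau_shape, cfg$tau_rate))
      two_arm <- "arm" %in% names(dat)
      spec <- model_spec(basis,
                         ph_covariates = if (two_arm) "arm" else character(0),
                         nonph_covariates =
                           if (two_arm && cfg$model_type == "bayes_nonph")
                             "arm" else character(0),
                         priors = pr)
      fit <- if (cfg$method == "mcmc")
        fit_mcmc(spec, dat, chains = chains, iterations = iterations,
                 seed = seed)
      else fit_laplace(spec, dat, n_draws = laplace_draws, seed = seed)
      est <- if (two_arm)
        rmstd(fit, x_active = c(arm = 1), x_control = c(arm = 0), horizon)
      else rmst(fit, x = NULL, horizon)
      rec$point <- est$median; rec$sd <- est$sd
      rec$lower <- est$lower; rec$upper <- est$upper
      if (cfg$method == "mcmc") {
        d <- fit$diagnostics
        rec$max_rhat <- d$max_rhat
        rec$min_ess <- d$min_bulk_ess
        rec$divergences <- sum(fit$divergences)
        rec$converged <- isTRUE(d$converged)
      }
    } else {
      fit <- fit_rp_mle(dat, baseline_df = cfg$df,
                        tve_df = if (cfg$model_type == "rp_tve")
                          cfg$tve_df else 0,
                        stratified = cfg$model_type == "rp_stratified")
      two_arm <- "arm" %in% names(dat)
      inf <- if (two_arm) rp_rmstd_inference(fit, horizon)
      else rp_rmst_inference(fit, 0, horizon, method = "delta")
      rec$point <- inf$estimate; rec$sd <- inf$se
      rec$lower <- inf$ci[1]; rec$upper <- inf$ci[2]
      rec$converged <- fit$converged
    }
    TRUE
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    rec$status <- paste("error:",
                        trimws(strsplit(attr(res, "condition")$message,
                                        "\n")[[1]][1]))
    rec$point <- rec$sd <- rec$lower <- rec$upper <- NA_real_
  }
  rec
}

#' Performance measures for one grid cell
#'
#' Standard simulation-study measures with Monte-Carlo standard errors:
#' bias (MCSE = empSE / sqrt(n)), relative bias (%), empirical SE
#' (MCSE = empSE / sqrt(2(n-1))), mean posterior SD / model SE, and coverage
#' of the 95% intervals (MCSE = sqrt(c(1-c)/n)). Non-converged or failed
#' replicates are excluded and counted. Relative bias is suppressed when
#' |truth| < 0.05 years (denominator too close to zero to be meaningful).
#'
#' @param records data frame of [run_single_rep()] records for one cell.
#' @param truth true estimand value.
#' @param exclude_nonconverged drop replicates with max split-Rhat > 1.05.
#' @return one-row data frame of performance measures.
#' @export
performance <- function(records, truth, exclude_nonconverged = TRUE) {
  ok <- records$status == "ok" & is.finite(records$point)
  n_failed <- sum(!ok)
  use <- ok
  if (exclude_nonconverged) use <- use & records$converged
  n_nonconv <- sum(ok & !records$converged)
  r <- records[use, , drop = FALSE]
  n <- nrow(r)
  if (n < 2) stop("need at least 2 usable replicates")
  emp_se <- stats::sd(r$point)
  bias <- mean(r$point) - truth
  cover <- mean(r$lower <= truth & truth <= r$upper)
  data.frame(
    truth = truth, n_reps = n, n_failed = n_failed,
    n_nonconverged = n_nonconv,
    mean_est = mean(r$point),
    bias = bias, bias_mcse = emp_se / sqrt(n),
    rel_bias_pct = if (abs(truth) >= 0.05) 100 * bias / truth else NA_real_,
    rel_bias_mcse = if (abs(truth) >= 0.05)
      100 * emp_se / sqrt(n) / abs(truth) else NA_real_,
    emp_se = emp_se, emp_se_mcse = emp_se / sqrt(2 * (n - 1)),
    mean_post_sd = mean(r$sd),
    mean_post_sd_mcse = stats::sd(r$sd) / sqrt(n),
    coverage = cover, coverage_mcse = sqrt(cover * (1 - cover) / n),
    divergence_mean = mean(r$divergences, na.rm = TRUE))
}

#' Run a full simulation grid
#'
#' Loops cells x replicates with deterministic per-replicate seeds (results
#' are independent of the worker count), optionally in parallel, optionally
#' resuming from per-cell record files in `out_dir`.
#'
#' @param grid a [sim_grid()].
#' @param reps replicates per cell.
#' @param master_seed master seed.
#' @param truth true estimand value (computed from the grid's DGM via
#'   [true_estimands()] when NULL).
#' @param workers parallel workers (forked; 1 = serial).
#' @param out_dir if given, per-cell records are written to (and resumed
#'   from) `records_cell<k>.csv` files there.
#' @param ... passed to [run_single_rep()] (e.g. `iterations`).
#' @return list with `performance` (one row per cell, cell settings bound)
#'   and `records`.
#' @export
run_grid <- function(grid, reps, master_seed = 1, truth = NULL, workers = 1,
                     out_dir = NULL, ...) {
  if (is.null(truth)) {
    te <- true_estimands(resolve_dgm(attr(grid, "dgm")),
                         resolve_scenario(attr(grid, "scenario")),
                         horizon = attr(grid, "horizon"))
    truth <- if (is.null(te$rmstd)) te$rmst_control else te$rmstd
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  all_rec <- list()
  for (cell in grid$cell) {
    f <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("records_cell%d.csv", cell)) else NULL
    if (!is.null(f) && file.exists(f)) {
      prev <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (nrow(prev) >= reps) {
        all_rec[[length(all_rec) + 1]] <- prev[seq_len(reps), ]
        next
      }
    }
    one <- function(rp) run_single_rep(grid, cell, rp, master_seed, ...)
    recs <- if (workers > 1)
      do.call(rbind, parallel::mclapply(seq_len(reps), one,
                                        mc.cores = workers))
    else do.call(rbind, lapply(seq_len(reps), one))
    if (!is.null(f)) utils::write.csv(recs, f, row.names = FALSE)
    all_rec[[length(all_rec) + 1]] <- recs
  }
  records <- do.call(rbind, all_rec)
  perf <- do.call(rbind, lapply(grid$cell, function(cell) {
    cbind(grid[grid$cell == cell, , drop = FALSE],
          performance(records[records$cell == cell, ], truth))
  }))
  rownames(perf) <- NULL
  list(performance = perf, records = records, truth = truth)
}

#' Write tidy report tables
#'
#' One CSV of performance rows and one of raw records.
#'
#' @param result a [run_grid()] result.
#' @param out_dir output directory.
#' @return vector of written file paths, invisibly.
#' @export
report_tables <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(out_dir, "performance.csv")
  f2 <- file.path(out_dir, "records.csv")
  utils::write.csv(result$performance, f1, row.names = FALSE)
  utils::write.csv(result$records, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
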