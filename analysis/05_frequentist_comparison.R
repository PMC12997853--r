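#!/usr/bin/env Rscript
## Frequentist Royston-Parmar comparators: maximum-likelihood spline fits
## with 2, 3, 4, 6 and 10 baseline df on single-arm data from each fixture,
## estimating 5-year RMST with delta-method standard errors. 100 replicates
## per cell. The df = 2 model is the Weibull; under-parameterised fits are
## expected to show visible bias on both fixtures.

library(msplinesurv)

reps <- 100
dfs <- c(2, 3, 4, 6, 10)
fx <- fixture_dgms()
rows <- list()
for (dgm_name in c("os_like", "pfs_like")) {
  dgm <- fx[[dgm_name]]
  truth <- true_estimands(dgm, horizon = 5)$rmst_control
  seeds <- msplinesurv:::rep_seeds(31, reps)
  for (df in dfs) {
    est <- se <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      dat <- simulate_trial(dgm, NULL, n_per_arm = 200,
                            admin_censor_time = 5, seed = seeds[r])
      fit <- try(fit_rp_mle(dat, baseline_df = df), silent = TRUE)
      if (inherits(fit, "try-error") || is.null(fit$vcov)) next
      inf <- rp_rmst_inference(fit, 0, 5, method = "delta")
      est[r] <- inf$estimate
      se[r] <- inf$se
    }
    ok <- is.finite(est)
    lo <- est - 1.96 * se; hi <- est + 1.96 * se
    rows[[length(rows) + 1]] <- data.frame(
      dgm = dgm_name, df = df, truth = truth, n_ok = sum(ok),
      rel_bias_pct = 100 * (mean(est[ok]) - truth) / truth,
      emp_se = sd(est[ok]), mean_model_se = mean(se[ok]),
      coverage = mean(lo[ok] <= truth & truth <= hi[ok]))
  }
}

tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/frequentist_performance.csv", row.names = FALSE)
print(tab, digits = 3)

cat("\nReading guide: relative bias should be small for df >= 3 (os_like)",
    "and df >= 4 (pfs_like), with the Weibull (df = 2) visibly biased on",
    "both; model SEs should track the empirical SEs when the fit is",
    "adequate.\n")
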