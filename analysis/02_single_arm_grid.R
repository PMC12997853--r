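#!/usr/bin/env Rscript
## Single-arm simulation study: the 18-model Bayesian grid (df x smoothness
## prior x coefficient model) fitted to replicated trials drawn from each
## fixture truth. Laplace fits keep this desk-size run tractable (100
## replicates per cell here; the full-MCMC calibration run for the default
## model is in 03_calibration.R).

library(msplinesurv)

reps <- 100
out <- list()
for (dgm in c("os_like", "pfs_like")) {
  g <- sim_grid(dgm = dgm, method = "laplace")
  res <- run_grid(g, reps = reps, master_seed = 42,
                  out_dir = file.path("results", "records", dgm))
  perf <- res$performance
  perf$dgm <- dgm
  out[[dgm]] <- perf
  cat(sprintf("\n%s (truth RMST5 = %.3f):\n", dgm, res$truth))
  print(perf[, c("df", "sigma_rate", "coef", "rel_bias_pct", "emp_se",
                 "mean_post_sd", "coverage")], digits = 3)
}

tab <- do.call(rbind, out)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/single_arm_performance.csv", row.names = FALSE)

cat("\nKey patterns to look for: low relative bias for flexible models",
    "(df = 10) under the Gamma(2,1) smoothness prior; rising bias as the",
    "prior tightens to Gamma(2,20), strongest on the sharply varying",
    "pfs_like hazard at low df.\n")
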