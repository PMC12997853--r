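#!/usr/bin/env Rscript
## Two-arm treatment-effect study: the os_like control arm with each of the
## four hazard-ratio scenarios (constant 0.7, waning, delayed-then-waning,
## crossing). For every scenario we fit the proportional-hazards model and
## non-PH models with df in {3, 6, 10} and the non-proportionality prior
## tau varied over Gamma(2,1) / Gamma(2,5) / Gamma(2,20), estimating the
## 5-year RMST difference. Laplace fits, 50 replicates per cell, keep this
## run desk-sized.

library(msplinesurv)

reps <- 50
out <- list()
for (sc in c("s1", "s2", "s3", "s4")) {
  g_ph <- sim_grid(dgm = "os_like", scenario = sc, model_type = "bayes_ph",
                   df = 10, sigma_prior = list(c(2, 1)),
                   coef_model = "random_walk", method = "laplace")
  g_np <- sim_grid(dgm = "os_like", scenario = sc,
                   model_type = "bayes_nonph",
                   df = c(3, 6, 10), sigma_prior = list(c(2, 1)),
                   coef_model = "random_walk",
                   tau_prior = list(c(2, 1), c(2, 5), c(2, 20)),
                   method = "laplace")
  res_ph <- run_grid(g_ph, reps = reps, master_seed = 11,
                     out_dir = file.path("results", "records",
                                         paste0(sc, "_ph")))
  res_np <- run_grid(g_np, reps = reps, master_seed = 11,
                     out_dir = file.path("results", "records",
                                         paste0(sc, "_nonph")))
  perf <- rbind(res_ph$performance, res_np$performance)
  perf$scenario <- sc
  out[[sc]] <- perf
  cat(sprintf("\nscenario %s (true RMSTD5 = %.3f):\n", sc, res_ph$truth))
  print(perf[, c("model_type", "df", "tau_rate", "rel_bias_pct", "emp_se",
                 "mean_post_sd", "coverage")], digits = 3)
}

tab <- do.call(rbind, out)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/two_arm_performance.csv", row.names = FALSE)

cat("\nExpected qualitative pattern: the PH model is competitive under the",
    "constant-HR scenario; under waning effects the non-PH models with",
    "weak tau smoothing track the time-varying hazard ratio, while a",
    "Gamma(2,20) tau prior flattens it back toward the PH fit.\n")
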