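## Model fitting: adaptive HMC (full MCMC) and a Laplace approximation at the
## posterior mode, both on the unconstrained parameterisation.

## Precompute the design pieces the C++ log posterior needs.
make_model_data <- function(spec, data) {
  check_surv_data(data, spec)
  if (sum(data$event) == 0)
    stop("no observed events: the hazard scale is not identified")
  b <- spec$basis
  if (any(data$time > b$upper + 1e-12))
    stop("observation times beyond the basis upper boundary")
  ev <- data$event == 1
  P <- length(spec$ph_covariates); Q <- length(spec$nonph_covariates)
  xm <- function(nms, rows) {
    if (!length(nms)) return(matrix(0, sum(rows | TRUE), 0)[rows, , drop = FALSE])
    as.matrix(data[rows, nms, drop = FALSE])
  }
  all_rows <- rep(TRUE, nrow(data))
  list(B_ev = eval_msplines(b, data$time[ev]),
       I_all = eval_isplines(b, data$time),
       Xph_ev = xm(spec$ph_covariates, ev),
       Xph_all = xm(spec$ph_covariates, all_rows),
       Xnp_ev = xm(spec$nonph_covariates, ev),
       Xnp_all = xm(spec$nonph_covariates, all_rows),
       mu = spec$mu, w = spec$w,
       coef_model = if (spec$priors$coef_model == "random_walk") 0L else 1L,
       eta_mean = spec$priors$log_scale_prior[1],
       eta_sd = spec$priors$log_scale_prior[2],
       sigma_shape = spec$priors$sigma_prior[1],
       sigma_rate = spec$priors$sigma_prior[2],
       beta_mean = rep(spec$priors$beta_prior[1], P),
       beta_sd = rep(spec$priors$beta_prior[2], P),
       tau_shape = spec$priors$tau_prior[1],
       tau_rate = spec$priors$tau_prior[2])
}

## Crude data-driven initial values (constant hazard at the crude event
## rate), jittered per chain.
init_theta <- function(spec, data, jitter = 0) {
  ix <- par_layout(spec)
  th <- numeric(spec$n_par)
  rate <- sum(data$event) / sum(data$time)
  th[ix$log_eta] <- log(rate) + log(spec$basis$upper - spec$basis$lower)
  th[ix$log_sigma] <- 0
  th <- th + jitter * stats::rnorm(length(th), 0, 0.1)
  th
}

#' Fit the Bayesian M-spline model by MCMC
#'
#' Adaptive Hamiltonian Monte Carlo on the unconstrained parameterisation:
#' warmup adapts a dual-averaged step size and a diagonal mass matrix; half of
#' `iterations` are warmup, so the default 4 chains of 2,000 iterations retain
#' 4 x 1,000 draws.
#'
#' @param spec a [model_spec()].
#' @param data survival data frame (`time`, `event`, covariates).
#' @param chains number of chains (default 4).
#' @param iterations iterations per chain, warmup included (default 2000).
#' @param seed integer RNG seed; same seed gives identical draws.
#' @param target_accept HMC acceptance target (default 0.9).
#' @param sim_length Hamiltonian trajectory length in mass-standardised
#'   space (default 2); the leapfrog step count per iteration is drawn
#'   uniformly up to `sim_length / stepsize`.
#' @return object of class `mspline_fit`: unconstrained `draws`
#'   (matrix, with `chain` attribute), the `spec`, per-chain `divergences`,
#'   a `method` tag and `diagnostics` (see [fit_diagnostics()]).
#' @export
fit_mcmc <- function(spec, data, chains = 4, iterations = 2000, seed = 1,
                     target_accept = 0.9, sim_length = 2) {
  md <- make_model_data(spec, data)
  n_warm <- floor(iterations / 2)
  n_samp <- iterations - n_warm
  set.seed(seed)
  res <- vector("list", chains)
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(chains)) {
    init <- init_theta(spec, data, jitter = 1)
    res[[ch]] <- hmc_chain(md, init, n_warm, n_samp,
                           target_accept = target_accept,
                           sim_length = sim_length)
  }
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  colnames(draws) <- par_names(spec)
  attr(draws, "chain") <- rep(seq_len(chains), each = n_samp)
  fit <- structure(list(
    draws = draws, spec = spec, method = "mcmc",
    chains = chains, iterations = iterations, seed = seed,
    divergences = vapply(res, `[[`, numeric(1), "divergences"),
    accept_rate = vapply(res, `[[`, numeric(1), "accept_rate"),
    runtime = proc.time()[["elapsed"]] - t0,
    n_events = sum(data$event), n = nrow(data)), class = "mspline_fit")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

par_names <- function(spec) {
  nb <- spec$n_basis
  c("log_eta", if (nb > 1) paste0("eps", 2:nb), "log_sigma",
    if (length(spec$ph_covariates)) paste0("beta_", spec$ph_covariates),
    if (length(spec$nonph_covariates))
      as.vector(outer(2:nb, spec$nonph_covariates,
                      function(i, s) paste0("delta", i, "_", s))),
    if (length(spec$nonph_covariates))
      paste0("log_tau_", spec$nonph_covariates))
}

#' Fit by Laplace approximation at the posterior mode
#'
#' Maximises the unconstrained log posterior by BFGS with analytic gradients
#' (restarting from perturbed initials on failure), forms a Gaussian
#' approximation with covariance equal to the inverse Hessian at the mode,
#' and draws `n_draws` samples from it. Point estimates reported downstream
#' are posterior medians of these draws, as for MCMC.
#'
#' @inheritParams fit_mcmc
#' @param n_draws number of Gaussian approximation draws (default 4000).
#' @param max_restarts optimisation restarts before giving up.
#' @return an `mspline_fit` with `method = "laplace"`, carrying the `mode`
#'   and unconstrained covariance `vcov`.
#' @export
fit_laplace <- function(spec, data, n_draws = 4000, seed = 1,
                        max_restarts = 5) {
  md <- make_model_data(spec, data)
  negp <- function(th) -mspline_logpost_grad(md, th)$lp
  negg <- function(th) -mspline_logpost_grad(md, th)$grad
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  best <- NULL
  for (r in 0:max_restarts) {
    init <- init_theta(spec, data, jitter = if (r == 0) 0 else 1)
    opt <- try(stats::optim(init, negp, negg, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(opt, "try-error") && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(best) && r >= 1) break
  }
  if (is.null(best)) stop("Laplace optimisation failed after restarts")
  mode <- best$par
  H <- numeric_hessian(function(th) -mspline_logpost_grad(md, th)$grad, mode)
  H <- (H + t(H)) / 2
  eg <- eigen(H, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("Hessian at the mode is not positive definite in direction(s) ",
         paste(which(eg$values <= 0), collapse = ", "))
  ## draws ~ N(mode, H^{-1})
  Lhalf <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  z <- matrix(stats::rnorm(n_draws * length(mode)), n_draws)
  draws <- sweep(z %*% t(Lhalf), 2, mode, `+`)
  colnames(draws) <- par_names(spec)
  attr(draws, "chain") <- rep(1L, n_draws)
  structure(list(
    draws = draws, spec = spec, method = "laplace",
    mode = stats::setNames(mode, par_names(spec)),
    vcov = Lhalf %*% t(Lhalf),
    seed = seed, converged = best$convergence == 0,
    runtime = proc.time()[["elapsed"]] - t0,
    n_events = sum(data$event), n = nrow(data)), class = "mspline_fit")
}

## central-difference Hessian of a gradient function
numeric_hessian <- function(grad_fn, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    H[i, ] <- (grad_fn(xp) - grad_fn(xm)) / (2 * h)
  }
  H
}

#' @export
print.mspline_fit <- function(x, ...) {
  cat(sprintf("Bayesian M-spline hazard fit (%s): %d draws, %d parameters\n",
              x$method, nrow(x$draws), ncol(x$draws)))
  if (x$method == "mcmc") {
    d <- x$diagnostics
    cat(sprintf("  max split-Rhat %.3f, min bulk ESS %.0f, divergences %s\n",
                d$max_rhat, d$min_bulk_ess,
                paste(x$divergences, collapse = "/")))
  }
  invisible(x)
}

## ---- convergence diagnostics (rank-normalised split-Rhat, bulk ESS) ----

split_chains <- function(mat, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- mat[chain == ch, , drop = FALSE]
    half <- floor(nrow(v) / 2)
    out[[length(out) + 1]] <- v[seq_len(half), , drop = FALSE]
    out[[length(out) + 1]] <- v[(half + 1):(2 * half), , drop = FALSE]
  }
  out
}

rank_normalise <- function(chains_1d) {
  all <- unlist(chains_1d)
  r <- rank(all, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(all) + 1 / 4))
  lens <- vapply(chains_1d, length, integer(1))
  split(z, rep(seq_along(chains_1d), lens))
}

rhat_ess_1d <- function(chains_1d) {
  m <- length(chains_1d); n <- length(chains_1d[[1]])
  if (stats::var(unlist(chains_1d)) < 1e-300)
    return(c(rhat = NA_real_, ess = NA_real_))
  zc <- rank_normalise(chains_1d)
  means <- vapply(zc, mean, numeric(1))
  vars <- vapply(zc, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  varplus <- (n - 1) / n * W + B / n
  rhat <- sqrt(varplus / W)
  ## bulk ESS from combined autocorrelations (Geyer initial monotone sequence)
  acov <- sapply(zc, function(z) {
    a <- stats::acf(z, lag.max = n - 1, plot = FALSE, type = "covariance")
    as.vector(a$acf)
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / varplus
  ## paired sums, truncated at first negative, enforced monotone
  maxpair <- floor(length(rho) / 2) - 1
  psum <- numeric(0)
  for (k in 0:maxpair) {
    s <- rho[2 * k + 1] + if (2 * k + 2 <= length(rho)) rho[2 * k + 2] else 0
    if (s < 0) break
    psum <- c(psum, s)
  }
  if (length(psum) > 1) psum <- cummin(psum)
  tau_int <- -1 + 2 * sum(psum)
  ess <- m * n / max(tau_int, 1 / (m * n))
  c(rhat = rhat, ess = min(ess, m * n * log10(m * n)))
}

#' Convergence diagnostics for an MCMC fit
#'
#' Rank-normalised split-\eqn{\hat R} and bulk effective sample size per
#' parameter, with the convergence flags used in reporting: converged when
#' max \eqn{\hat R \le 1.05}, adequate ESS when min bulk ESS \eqn{\ge 400}.
#'
#' @param fit an `mspline_fit` (or a draws matrix with a `chain` attribute).
#' @return list with per-parameter `rhat` and `bulk_ess`, `max_rhat`,
#'   `min_bulk_ess`, `converged`, `adequate_ess`, `divergence` counts and
#'   proportions (MCMC fits).
#' @export
fit_diagnostics <- function(fit) {
  draws <- if (inherits(fit, "mspline_fit")) fit$draws else fit
  chain <- attr(draws, "chain")
  n_chain <- length(unique(chain))
  if (n_chain < 2) {
    return(list(rhat = rep(NA_real_, ncol(draws)),
                bulk_ess = rep(NA_real_, ncol(draws)),
                max_rhat = NA_real_, min_bulk_ess = NA_real_,
                converged = NA, adequate_ess = NA,
                note = "split-Rhat requires >= 2 chains"))
  }
  sc <- split_chains(draws, chain)
  stats_mat <- vapply(seq_len(ncol(draws)), function(j) {
    rhat_ess_1d(lapply(sc, function(m) m[, j]))
  }, numeric(2))
  rhat <- stats_mat[1, ]; ess <- stats_mat[2, ]
  names(rhat) <- names(ess) <- colnames(draws)
  degenerate <- all(is.na(rhat))
  out <- list(rhat = rhat, bulk_ess = ess,
              max_rhat = if (degenerate) NA_real_ else max(rhat, na.rm = TRUE),
              min_bulk_ess = if (degenerate) NA_real_ else min(ess, na.rm = TRUE),
              degenerate = degenerate)
  out$converged <- if (degenerate) NA else out$max_rhat <= 1.05
  out$adequate_ess <- if (degenerate) NA else out$min_bulk_ess >= 400
  if (inherits(fit, "mspline_fit") && !is.null(fit$divergences)) {
    out$divergences <- fit$divergences
    out$divergence_prop <- fit$divergences /
      (nrow(fit$draws) / length(fit$divergences))
  }
  out
}

#' Serialise a fit to a directory
#'
#' Writes the draws as CSV, the diagnostics as JSON and a config echo.
#'
#' @param fit an `mspline_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dd <- as.data.frame(fit$draws)
  dd$chain <- attr(fit$draws, "chain")
  utils::write.csv(dd, file.path(dir, "draws.csv"), row.names = FALSE)
  diag <- fit$diagnostics
  if (is.null(diag)) diag <- list(method = fit$method)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(method = fit$method, seed = fit$seed, n = fit$n,
              n_events = fit$n_events,
              n_basis = fit$spec$n_basis,
              coef_model = fit$spec$priors$coef_model)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
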