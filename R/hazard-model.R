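#' Prior specification for the Bayesian M-spline hazard model
#'
#' Defaults follow the weakly informative settings used throughout:
#' \eqn{\log\eta \sim N(0, 20)} (SD 20), \eqn{\sigma \sim Gamma(2, 1)}
#' (shape-rate), PH log hazard ratios \eqn{\beta \sim N(0, 20)}, and
#' non-proportionality scales \eqn{\tau_s \sim Gamma(2, 1)}.
#'
#' @param log_scale_prior length-2 numeric `(location, sd)` for `log eta`.
#' @param sigma_prior length-2 numeric `(shape, rate)` for the smoothness
#'   parameter `sigma`.
#' @param coef_model `"random_walk"` (weighted logistic random walk on the
#'   spline random effects) or `"exchangeable"` (iid Logistic(0, 1)).
#' @param beta_prior length-2 numeric `(location, sd)` for each PH
#'   log-hazard-ratio.
#' @param tau_prior length-2 numeric `(shape, rate)` for each `tau_s`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(log_scale_prior = c(0, 20),
                       sigma_prior = c(2, 1),
                       coef_model = c("random_walk", "exchangeable"),
                       beta_prior = c(0, 20),
                       tau_prior = c(2, 1)) {
  coef_model <- match.arg(coef_model)
  stopifnot(log_scale_prior[2] > 0, sigma_prior[1] > 0, sigma_prior[2] > 0,
            beta_prior[2] > 0, tau_prior[1] > 0, tau_prior[2] > 0)
  structure(list(log_scale_prior = log_scale_prior, sigma_prior = sigma_prior,
                 coef_model = coef_model, beta_prior = beta_prior,
                 tau_prior = tau_prior),
            class = "prior_spec")
}

#' Model specification: basis, covariate roles, priors
#'
#' @param basis an [mspline_basis()].
#' @param ph_covariates character vector of covariates with proportional
#'   (time-constant) effects on the hazard scale.
#' @param nonph_covariates character vector of covariates whose effects shift
#'   the spline weights (time-varying effects); must be a subset of
#'   `ph_covariates` — a non-PH covariate keeps its scale effect `beta` and
#'   adds departures `delta`.
#' @param priors a [prior_spec()].
#' @return object of class `model_spec`.
#' @export
model_spec <- function(basis, ph_covariates = character(0),
                       nonph_covariates = character(0),
                       priors = prior_spec()) {
  stopifnot(inherits(basis, "mspline_basis"), inherits(priors, "prior_spec"))
  if (!all(nonph_covariates %in% ph_covariates))
    stop("non-PH covariates must also appear in `ph_covariates` ",
         "(they retain a scale effect beta)")
  nb <- basis$n_basis
  pc <- const_hazard_coefs(basis)
  structure(list(
    basis = basis, ph_covariates = ph_covariates,
    nonph_covariates = nonph_covariates, priors = priors,
    mu = log(pc / pc[1]),        # multinomial-logit means: constant hazard
    w = rw_weights(basis),
    n_basis = nb,
    n_par = 1 + (nb - 1) + 1 + length(ph_covariates) +
      (nb - 1) * length(nonph_covariates) + length(nonph_covariates)),
    class = "model_spec")
}

## Index helpers for the unconstrained parameter vector
## [log_eta, eps_2..nb, log_sigma, beta, delta (per non-PH cov), log_tau].
## Centred parameterisation: the sampled coordinates are the random effects
## eps, with gamma_i = mu_i + sigma * eps_i derived; the joint density is
## bounded there (in gamma-coordinates it diverges as sigma -> 0).
par_layout <- function(spec) {
  nb <- spec$n_basis
  P <- length(spec$ph_covariates); Q <- length(spec$nonph_covariates)
  list(log_eta = 1L,
       eps = if (nb > 1) 2L:nb else integer(0),
       log_sigma = nb + 1L,
       beta = if (P) (nb + 1L) + seq_len(P) else integer(0),
       delta = if (Q) (nb + 1L + P) + seq_len((nb - 1) * Q) else integer(0),
       log_tau = if (Q) (nb + 1L + P + (nb - 1) * Q) + seq_len(Q) else integer(0))
}

#' Assemble a named parameter list from an unconstrained vector
#'
#' @param theta numeric vector on the unconstrained scale.
#' @param spec a [model_spec()].
#' @return list with `eta`, `eps` (random effects, length `n_basis`, first
#'   element 0), the derived baseline logits `gamma = mu + sigma * eps`,
#'   `sigma`, `beta`, `delta` (matrix `n_basis` by number of non-PH
#'   covariates, first row 0), `tau`.
#' @export
unpack_params <- function(theta, spec) {
  ix <- par_layout(spec)
  nb <- spec$n_basis
  Q <- length(spec$nonph_covariates)
  if (length(theta) != spec$n_par)
    stop("parameter vector has length ", length(theta), ", expected ",
         spec$n_par)
  delta <- matrix(0, nb, Q)
  if (Q) delta[-1, ] <- matrix(theta[ix$delta], nb - 1, Q)
  eps <- c(0, theta[ix$eps])
  sigma <- exp(theta[ix$log_sigma])
  list(eta = exp(theta[ix$log_eta]),
       eps = eps,
       gamma = spec$mu + sigma * eps,
       sigma = sigma,
       beta = stats::setNames(theta[ix$beta], spec$ph_covariates),
       delta = delta,
       tau = exp(theta[ix$log_tau]))
}

#' Spline weights for a covariate vector
#'
#' \eqn{\gamma_1(x) = 0}, \eqn{\gamma_i(x) = \gamma_i + \delta_i^T x} with
#' \eqn{\gamma_i = \mu_i + \sigma\epsilon_i}; the weights are the softmax
#' of \eqn{\gamma(x)}.
#'
#' @param theta unconstrained parameter vector.
#' @param spec a [model_spec()].
#' @param x named covariate vector (or NULL when the model has none).
#' @return simplex vector of length `n_basis`.
#' @export
spline_coefs <- function(theta, spec, x = NULL) {
  pp <- unpack_params(theta, spec)
  g <- pp$gamma
  if (length(spec$nonph_covariates)) {
    xv <- covariate_values(x, spec$nonph_covariates)
    g <- g + as.vector(pp$delta %*% xv)
  }
  ex <- exp(g - max(g))
  ex / sum(ex)
}

covariate_values <- function(x, nms) {
  if (!length(nms)) return(numeric(0))
  if (is.null(x)) stop("covariate values required for: ",
                       paste(nms, collapse = ", "))
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(nms)) names(x) <- nms
  miss <- setdiff(nms, names(x))
  if (length(miss)) stop("missing covariate values: ",
                         paste(miss, collapse = ", "))
  as.numeric(x[nms])
}

#' Hazard and cumulative hazard under the model
#'
#' \eqn{h(t|x) = \eta_0 e^{\beta^T x} \sum_i p_i(x) b_i(t)} and
#' \eqn{H(t|x) = \eta_0 e^{\beta^T x} \sum_i p_i(x) I_i(t)}.
#'
#' @inheritParams spline_coefs
#' @param t times in `[0, upper]`; larger times are an error (the basis does
#'   not extrapolate).
#' @return numeric vector of hazard (or cumulative hazard) values.
#' @export
model_hazard <- function(theta, spec, x = NULL, t) {
  check_t_range(t, spec$basis)
  p <- spline_coefs(theta, spec, x)
  eta_x(theta, spec, x) * as.vector(eval_msplines(spec$basis, t) %*% p)
}

#' @rdname model_hazard
#' @export
model_cumhaz <- function(theta, spec, x = NULL, t) {
  check_t_range(t, spec$basis)
  p <- spline_coefs(theta, spec, x)
  eta_x(theta, spec, x) * as.vector(eval_isplines(spec$basis, t) %*% p)
}

eta_x <- function(theta, spec, x) {
  pp <- unpack_params(theta, spec)
  sc <- pp$eta
  if (length(spec$ph_covariates)) {
    xv <- covariate_values(x, spec$ph_covariates)
    sc <- sc * exp(sum(pp$beta * xv))
  }
  sc
}

check_t_range <- function(t, basis) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("times must be >= 0")
  if (any(t > basis$upper + 1e-12))
    stop("time beyond the upper boundary knot (", basis$upper,
         "): hazard extrapolation is not supported")
  invisible(TRUE)
}

#' Right-censored log likelihood
#'
#' \eqn{\sum_{events} \log h(t_i|x_i) - \sum_{all} H(t_i|x_i)}.
#'
#' @param theta unconstrained parameter vector.
#' @param spec a [model_spec()].
#' @param data data frame with columns `time`, `event` (1 = observed event,
#'   0 = censored) and any covariates named in the model specification.
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(theta, spec, data) {
  check_surv_data(data, spec)
  covs <- union(spec$ph_covariates, spec$nonph_covariates)
  ll <- 0
  H_all <- vapply(seq_len(nrow(data)), function(j) {
    x <- if (length(covs)) data[j, covs, drop = FALSE] else NULL
    model_cumhaz(theta, spec, x, data$time[j])
  }, numeric(1))
  ev <- which(data$event == 1)
  logh <- vapply(ev, function(j) {
    x <- if (length(covs)) data[j, covs, drop = FALSE] else NULL
    log(model_hazard(theta, spec, x, data$time[j]))
  }, numeric(1))
  out <- sum(logh) - sum(H_all)
  if (!is.finite(out)) {
    bad <- which(!is.finite(c(logh, -H_all)))[1]
    stop("non-finite log likelihood (record ", bad, ")")
  }
  out
}

check_surv_data <- function(data, spec = NULL) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)))
  if (any(data$time < 0)) stop("negative survival times")
  if (!all(data$event %in% c(0, 1))) stop("`event` must be coded 0/1")
  if (!is.null(spec)) {
    covs <- union(spec$ph_covariates, spec$nonph_covariates)
    miss <- setdiff(covs, names(data))
    if (length(miss)) stop("data lack covariates: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

dlogis_log <- function(x, location, scale) {
  z <- (x - location) / scale
  -z - 2 * log1p(exp(-z)) - log(scale)
}

#' Log prior density on the unconstrained scale
#'
#' Sum of the log prior densities for `log eta`, the spline random effects
#' `eps` (weighted logistic random walk or exchangeable Logistic(0,1)),
#' `sigma` and each `tau_s` (gamma, with the log-Jacobian for the log
#' transform), each `beta` (normal) and each `delta_is ~ N(0, tau_s)`.
#'
#' @inheritParams log_likelihood
#' @return scalar log prior density.
#' @export
log_prior <- function(theta, spec) {
  pp <- unpack_params(theta, spec)
  pr <- spec$priors
  ix <- par_layout(spec)
  nb <- spec$n_basis
  lp <- stats::dnorm(theta[ix$log_eta], pr$log_scale_prior[1],
                     pr$log_scale_prior[2], log = TRUE)
  eps <- pp$eps
  if (pr$coef_model == "random_walk") {
    lp <- lp + sum(dlogis_log(eps[-1], eps[-nb], spec$w))
  } else {
    lp <- lp + sum(dlogis_log(eps[-1], 0, 1))
  }
  ## gamma log density + log-Jacobian for sigma = exp(log_sigma)
  lp <- lp + stats::dgamma(pp$sigma, pr$sigma_prior[1], pr$sigma_prior[2],
                           log = TRUE) + theta[ix$log_sigma]
  if (length(ix$beta))
    lp <- lp + sum(stats::dnorm(theta[ix$beta], pr$beta_prior[1],
                                pr$beta_prior[2], log = TRUE))
  Q <- length(spec$nonph_covariates)
  if (Q) {
    for (q in seq_len(Q)) {
      lp <- lp + sum(stats::dnorm(pp$delta[-1, q], 0, pp$tau[q], log = TRUE))
      lp <- lp + stats::dgamma(pp$tau[q], pr$tau_prior[1], pr$tau_prior[2],
                               log = TRUE) + theta[ix$log_tau][q]
    }
  }
  lp
}

#' Prior-predictive variability of the hazard
#'
#' Draws parameters from the prior and, for each draw, computes the ratio of
#' the 90% to the 10% quantile of `h(t)` over a time grid — a scale-free
#' summary of how much the hazard varies with time under the prior. Used to
#' calibrate the smoothness prior on `sigma`.
#'
#' @param spec a [model_spec()] (baseline model; covariates at zero).
#' @param n_draws number of prior draws.
#' @param t_grid evaluation grid within the basis support (default 50 points
#'   over the support, excluding the exact endpoints).
#' @param seed integer RNG seed.
#' @return list with the draw-wise `ratios`, the `median` and the
#'   `upper90` (90% quantile) of their distribution.
#' @export
prior_hazard_variability <- function(spec, n_draws = 1000, t_grid = NULL,
                                     seed = 1) {
  set.seed(seed)
  b <- spec$basis
  if (is.null(t_grid))
    t_grid <- seq(b$lower + 1e-6 * (b$upper - b$lower), b$upper,
                  length.out = 50)
  Bm <- eval_msplines(b, t_grid)
  pr <- spec$priors
  nb <- spec$n_basis
  ratios <- vapply(seq_len(n_draws), function(d) {
    sigma <- stats::rgamma(1, pr$sigma_prior[1], pr$sigma_prior[2])
    if (pr$coef_model == "random_walk") {
      inc <- stats::rlogis(nb - 1, 0, spec$w)
      eps <- c(0, cumsum(inc))
    } else {
      eps <- c(0, stats::rlogis(nb - 1, 0, 1))
    }
    g <- spec$mu + sigma * eps
    p <- exp(g - max(g)); p <- p / sum(p)
    h <- as.vector(Bm %*% p)     # eta cancels in the ratio
    q <- stats::quantile(h, c(0.1, 0.9), type = 7)
    q[[2]] / q[[1]]
  }, numeric(1))
  list(ratios = ratios, median = stats::median(ratios),
       upper90 = unname(stats::quantile(ratios, 0.9)))
}
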