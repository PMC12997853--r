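## Posterior summaries: survival, hazard and hazard-ratio curves, restricted
## mean survival time (RMST) and its between-arm difference (RMSTD).

## Per-draw spline weights and hazard scale for a covariate vector.
## Vectorised over draws: returns P (n_draws x n_basis) and scale (n_draws).
draws_coefs <- function(fit, x = NULL) {
  spec <- fit$spec
  draws <- fit$draws
  ix <- par_layout(spec)
  nb <- spec$n_basis
  sigma <- exp(draws[, ix$log_sigma])
  eps <- cbind(0, draws[, ix$eps, drop = FALSE])
  G <- matrix(spec$mu, nrow(draws), nb, byrow = TRUE) + sigma * eps
  Q <- length(spec$nonph_covariates)
  if (Q) {
    xv <- covariate_values(x, spec$nonph_covariates)
    D <- draws[, ix$delta, drop = FALSE]      # (nb-1)*Q columns, stacked by cov
    for (q in seq_len(Q)) {
      if (xv[q] != 0) {
        cols <- ((q - 1) * (nb - 1) + 1):(q * (nb - 1))
        G[, -1] <- G[, -1] + xv[q] * D[, cols, drop = FALSE]
      }
    }
  }
  G <- G - apply(G, 1, max)
  P <- exp(G)
  P <- P / rowSums(P)
  scale <- exp(draws[, ix$log_eta])
  if (length(spec$ph_covariates)) {
    xv <- covariate_values(x, spec$ph_covariates)
    B <- draws[, ix$beta, drop = FALSE]
    scale <- scale * exp(as.vector(B %*% xv))
  }
  list(P = P, scale = scale)
}

## per-draw curves on a time grid: n_draws x length(t_grid)
draw_hazard_matrix <- function(fit, x, t_grid) {
  check_t_range(t_grid, fit$spec$basis)
  dc <- draws_coefs(fit, x)
  dc$scale * (dc$P %*% t(eval_msplines(fit$spec$basis, t_grid)))
}

draw_cumhaz_matrix <- function(fit, x, t_grid) {
  check_t_range(t_grid, fit$spec$basis)
  dc <- draws_coefs(fit, x)
  dc$scale * (dc$P %*% t(eval_isplines(fit$spec$basis, t_grid)))
}

curve_summary <- function(mat, t_grid) {
  qs <- apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE)
  data.frame(t = t_grid, median = qs[1, ], lower = qs[2, ], upper = qs[3, ])
}

#' Posterior survival and hazard curves
#'
#' Per-draw \eqn{S(t|x) = \exp(-H(t|x))} and \eqn{h(t|x)}, summarised
#' pointwise by the posterior median and equal-tailed 95% credible interval.
#'
#' @param fit an `mspline_fit`.
#' @param x named covariate values (NULL for a baseline / no-covariate model).
#' @param t_grid times within the basis support.
#' @return list with data frames `survival` and `hazard`
#'   (columns `t`, `median`, `lower`, `upper`).
#' @export
survival_and_hazard <- function(fit, x = NULL, t_grid) {
  S <- exp(-draw_cumhaz_matrix(fit, x, t_grid))
  h <- draw_hazard_matrix(fit, x, t_grid)
  list(survival = curve_summary(S, t_grid), hazard = curve_summary(h, t_grid))
}

#' Gauss-Legendre nodes and weights on [0, 1]
#'
#' Golub-Welsch eigenvalue construction; 100 nodes are used for all
#' cumulative-hazard and RMST quadrature.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights` (both on `[0, 1]`, weights sum 1).
#' @export
gauss_legendre <- function(n = 100) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  eg <- eigen(J, symmetric = TRUE)
  x <- eg$values                     # nodes on [-1, 1]
  w <- 2 * eg$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

#' Posterior restricted mean survival time
#'
#' Per draw, \eqn{RMST(T) = \int_0^T S(t|x)\,dt} by 100-node Gauss-Legendre
#' quadrature; summarised by the posterior median and equal-tailed 95%
#' credible interval.
#'
#' @inheritParams survival_and_hazard
#' @param horizon restriction time T (years), at most the basis upper
#'   boundary.
#' @param n_nodes quadrature nodes.
#' @return list with `draws` (per-draw RMST), `median`, `sd`, `lower`,
#'   `upper`.
#' @export
rmst <- function(fit, x = NULL, horizon, n_nodes = 100) {
  stopifnot(horizon >= 0)
  if (horizon > fit$spec$basis$upper + 1e-12)
    stop("RMST horizon beyond the basis upper boundary: no extrapolation")
  if (horizon == 0)
    return(list(draws = rep(0, nrow(fit$draws)), median = 0, sd = 0,
                lower = 0, upper = 0))
  gl <- gauss_legendre(n_nodes)
  tt <- horizon * gl$nodes
  S <- exp(-draw_cumhaz_matrix(fit, x, tt))
  d <- as.vector(S %*% (horizon * gl$weights))
  list(draws = d, median = stats::median(d), sd = stats::sd(d),
       lower = unname(stats::quantile(d, 0.025)),
       upper = unname(stats::quantile(d, 0.975)))
}

#' Posterior difference in RMST between two covariate profiles
#'
#' @inheritParams rmst
#' @param x_active,x_control covariate profiles for the two arms.
#' @return list with per-draw `draws`, `median`, `sd`, `lower`, `upper`.
#' @export
rmstd <- function(fit, x_active, x_control, horizon, n_nodes = 100) {
  a <- rmst(fit, x_active, horizon, n_nodes)
  c0 <- rmst(fit, x_control, horizon, n_nodes)
  d <- a$draws - c0$draws
  list(draws = d, median = stats::median(d), sd = stats::sd(d),
       lower = unname(stats::quantile(d, 0.025)),
       upper = unname(stats::quantile(d, 0.975)))
}

#' Posterior hazard-ratio curve between two covariate profiles
#'
#' Per-draw \eqn{h(t|x_{active}) / h(t|x_{control})}, summarised pointwise.
#' Grid points where the control-arm hazard underflows to zero are flagged
#' and returned as NA.
#'
#' @inheritParams rmstd
#' @param t_grid times within the basis support (avoid t = 0 where the cubic
#'   basis makes both hazards vanish).
#' @return data frame `t`, `median`, `lower`, `upper` with attribute
#'   `n_zero_hazard`.
#' @export
hazard_ratio_curve <- function(fit, x_active, x_control, t_grid) {
  ha <- draw_hazard_matrix(fit, x_active, t_grid)
  hc <- draw_hazard_matrix(fit, x_control, t_grid)
  zero <- hc <= 0
  hc[zero] <- NA_real_
  out <- curve_summary(ha / hc, t_grid)
  attr(out, "n_zero_hazard") <- sum(zero)
  out
}
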