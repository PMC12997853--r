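#' M-spline basis for hazard modelling
#'
#' An M-spline basis is a set of nonnegative polynomial spline functions
#' \eqn{b_i(t)}, each normalised to integrate to 1 over the basis support
#' \eqn{[lower, upper]}. A weighted sum \eqn{\sum_i p_i b_i(t)} with simplex
#' weights is therefore a smooth, positive function integrating to 1 times the
#' scale applied to it, which makes the family a convenient flexible model for
#' a hazard function.
#'
#' @param knots numeric vector of internal knot locations (years), strictly
#'   inside `(lower, upper)`; may be empty.
#' @param degree spline degree (cubic = 3, the default). Must be >= 1.
#' @param lower,upper boundary knots (years); `lower >= 0`, `upper > lower`.
#'
#' @return An object of class `mspline_basis` with elements `degree`,
#'   `knots` (full knot sequence with boundary knots repeated `degree + 1`
#'   times), `internal_knots`, `n_basis`, `lower`, `upper`.
#' @export
mspline_basis <- function(knots = numeric(0), degree = 3, lower = 0, upper) {
  stopifnot(is.numeric(degree), length(degree) == 1, degree >= 1)
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1)
  if (lower < 0) stop("`lower` must be >= 0")
  if (upper <= lower) stop("`upper` must be greater than `lower`")
  knots <- as.numeric(knots)
  if (any(!is.finite(knots))) stop("internal knots must be finite")
  if (any(knots <= lower | knots >= upper))
    stop("internal knots must lie strictly inside (lower, upper)")
  if (is.unsorted(knots)) knots <- sort(knots)
  if (anyDuplicated(knots)) {
    warning("duplicate internal knots collapsed to single knots")
    knots <- unique(knots)
  }
  full <- c(rep(lower, degree + 1), knots, rep(upper, degree + 1))
  structure(
    list(degree = degree, knots = full, internal_knots = knots,
         n_basis = length(knots) + degree + 1, lower = lower, upper = upper),
    class = "mspline_basis")
}

#' @export
print.mspline_basis <- function(x, ...) {
  cat(sprintf("M-spline basis: degree %d, %d basis functions on [%g, %g]\n",
              x$degree, x$n_basis, x$lower, x$upper))
  if (length(x$internal_knots))
    cat("internal knots:", paste(signif(x$internal_knots, 4), collapse = ", "),
        "\n")
  invisible(x)
}

#' Place knots at quantiles of the uncensored survival times
#'
#' Internal knots are placed at the equally spaced empirical quantiles
#' \eqn{i/(m+1)}, \eqn{i = 1, \dots, m} (type-7 quantiles), of the uncensored
#' event times, where `m = df - degree - 1`. Boundary knots default to 0 and
#' the maximum observed time.
#'
#' @param uncensored_times event (not censoring) times in years.
#' @param df number of basis functions; must be >= `degree + 1`.
#' @param degree spline degree, default cubic.
#' @param lower,upper boundary knots; `upper` defaults to the maximum of
#'   `all_times` (or of `uncensored_times` if `all_times` is missing).
#' @param all_times optional vector of all observed times (events and
#'   censorings) used for the default upper boundary.
#'
#' @return An `mspline_basis` with `n_basis = df` (fewer if tied quantiles
#'   collapse, with a warning).
#' @export
place_knots <- function(uncensored_times, df = 10, degree = 3, lower = 0,
                        upper = NULL, all_times = NULL) {
  if (df < degree + 1)
    stop("`df` must be at least degree + 1 = ", degree + 1)
  m <- df - degree - 1
  if (is.null(upper)) {
    tmax <- if (!is.null(all_times)) max(all_times) else max(uncensored_times)
    upper <- tmax
  }
  if (m > 0 && length(uncensored_times) == 0)
    stop("no uncensored event times available to place ", m, " internal knots")
  if (m > 0) {
    probs <- seq_len(m) / (m + 1)
    kn <- as.numeric(stats::quantile(uncensored_times, probs, type = 7))
    ## clip strictly inside the boundary; ties collapse inside mspline_basis()
    eps <- 1e-8 * (upper - lower)
    kn <- pmin(pmax(kn, lower + eps), upper - eps)
  } else kn <- numeric(0)
  mspline_basis(knots = kn, degree = degree, lower = lower, upper = upper)
}

## B-spline design matrix on the full knot sequence, zero outside support.
## splineDesign() drops points at/above the right boundary, so the evaluation
## at `upper` is taken as the left limit.
bspline_design <- function(full_knots, ord, t) {
  n_basis <- length(full_knots) - ord
  out <- matrix(0, length(t), n_basis)
  lower <- full_knots[1]; upper <- full_knots[length(full_knots)]
  inside <- t >= lower & t < upper
  at_up <- t == upper
  if (any(inside))
    out[inside, ] <- splines::splineDesign(full_knots, t[inside], ord = ord,
                                           outer.ok = TRUE)
  if (any(at_up)) {
    v <- splines::splineDesign(full_knots, upper - 1e-12 * max(1, upper),
                               ord = ord, outer.ok = TRUE)
    ## exact limit: the last basis function tends to 1 at the right boundary
    v[abs(v) < 1e-9] <- 0
    out[at_up, ] <- rep(v, each = sum(at_up))
  }
  out
}

#' Evaluate M-spline basis functions
#'
#' @param basis an [mspline_basis()].
#' @param t numeric vector of times; rows for `t` outside
#'   `[lower, upper]` are zero.
#' @return matrix `length(t)` by `n_basis` of nonnegative basis values.
#' @export
eval_msplines <- function(basis, t) {
  stopifnot(inherits(basis, "mspline_basis"), is.numeric(t), all(is.finite(t)))
  ord <- basis$degree + 1
  B <- bspline_design(basis$knots, ord, t)
  ## M_i = ord / (t_{i+ord} - t_i) * B_i  (normalised to unit integral)
  span <- basis$knots[seq_len(basis$n_basis) + ord] -
    basis$knots[seq_len(basis$n_basis)]
  sweep(B, 2, ord / span, `*`)
}

#' Evaluate integrated M-splines (I-splines)
#'
#' \eqn{I_i(t) = \int_{lower}^{t} b_i(u)\,du}; each column increases from 0 at
#' `lower` to 1 at `upper` and is 1 beyond `upper`.
#'
#' @inheritParams eval_msplines
#' @return matrix `length(t)` by `n_basis` of values in `[0, 1]`.
#' @export
eval_isplines <- function(basis, t) {
  stopifnot(inherits(basis, "mspline_basis"), is.numeric(t), all(is.finite(t)))
  ord <- basis$degree + 1
  ## integral of an M-spline is a tail sum of B-splines one order higher,
  ## on the knot sequence extended by one extra boundary knot at each end
  knots2 <- c(basis$lower, basis$knots, basis$upper)
  B2 <- bspline_design(knots2, ord + 1, t)      # n+1 columns
  n <- basis$n_basis
  out <- matrix(0, length(t), n)
  tail_sum <- t(apply(B2, 1, function(r) rev(cumsum(rev(r)))))
  if (length(t) == 1) tail_sum <- matrix(tail_sum, nrow = 1)
  out[, seq_len(n)] <- tail_sum[, seq_len(n) + 1, drop = FALSE]
  out[t >= basis$upper, ] <- 1
  out[t <= basis$lower, ] <- 0
  out
}

#' Coefficients giving a constant hazard
#'
#' The simplex weights under which the weighted M-spline sum is flat:
#' \eqn{p_i \propto t_{i+degree+1} - t_i}. These are the prior means of the
#' spline weights (on the multinomial-logit scale) in the Bayesian model.
#'
#' @inheritParams eval_msplines
#' @return simplex vector of length `n_basis`.
#' @export
const_hazard_coefs <- function(basis) {
  stopifnot(inherits(basis, "mspline_basis"))
  ord <- basis$degree + 1
  span <- basis$knots[seq_len(basis$n_basis) + ord] -
    basis$knots[seq_len(basis$n_basis)]
  span / sum(span)
}

#' Random-walk prior weights from knot spacing
#'
#' Weight \eqn{w_i} for the increment \eqn{\epsilon_i - \epsilon_{i-1}} is the
#' distance between the Greville abscissae (the mean of the `degree` interior
#' knots of each basis function's support) of basis functions \eqn{i-1} and
#' \eqn{i}, normalised to mean 1, so that coefficients of basis terms acting
#' on nearby regions of time are shrunk more strongly together. The Greville
#' points are strictly increasing for any valid knot sequence, so the weights
#' are always positive.
#'
#' @inheritParams eval_msplines
#' @return numeric vector of length `n_basis - 1` (weights for i = 2..n),
#'   positive with mean 1.
#' @export
rw_weights <- function(basis) {
  stopifnot(inherits(basis, "mspline_basis"))
  deg <- basis$degree
  grev <- vapply(seq_len(basis$n_basis), function(i)
    mean(basis$knots[(i + 1):(i + deg)]), numeric(1))
  g <- diff(grev)
  g / mean(g)
}
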