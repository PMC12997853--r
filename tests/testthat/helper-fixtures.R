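## Shared test fixtures, generated in code.

## exponential survival data with administrative censoring
exp_surv_data <- function(n = 200, rate = 0.5, censor = 5, seed = 1) {
  set.seed(seed)
  t <- stats::rexp(n, rate)
  data.frame(time = pmin(t, censor), event = as.integer(t < censor))
}

## trapezoid quadrature of basis columns on a dense grid
trapz_cols <- function(M, t) {
  dt <- diff(t)
  colSums((M[-1, , drop = FALSE] + M[-nrow(M), , drop = FALSE]) / 2 * dt)
}

## exact (composite Gauss-Legendre per knot span) integral of each basis
## column from `lower` up to `upto`; exact for polynomial splines
basis_integral_oracle <- function(b, upto = b$upper) {
  gl <- gauss_legendre(12)
  brk <- unique(c(b$knots[b$knots < upto], upto))
  out <- numeric(b$n_basis)
  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; z <- brk[k + 1]
    tt <- a + (z - a) * gl$nodes
    out <- out + (z - a) * as.vector(gl$weights %*% eval_msplines(b, tt))
  }
  out
}

## random basis generator for property-style tests
random_basis <- function(seed) {
  set.seed(seed)
  degree <- sample(1:3, 1)
  upper <- stats::runif(1, 2, 10)
  m <- sample(0:5, 1)
  kn <- if (m > 0) sort(stats::runif(m, 0.1 * upper, 0.9 * upper))
  else numeric(0)
  mspline_basis(knots = kn, degree = degree, lower = 0, upper = upper)
}

## cache expensive fits across tests within a run
.fit_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- force(expr)
  .fit_cache[[key]]
}

weibull_dgm <- function(shape = 1.3, scale = 3) {
  ## H(t) = (t / scale)^shape: a Royston-Parmar model with no internal knots
  rp_dgm(knots = log(c(0.01, 50)),
         coefs = c(-shape * log(scale), shape), label = "weibull")
}
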