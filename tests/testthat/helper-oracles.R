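# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# dense linear-algebra solution of the trend filter's normal equations
hp_dense_oracle <- function(y, lambda) {
  n <- length(y)
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i + 0:2] <- c(1, -2, 1)
  as.numeric(solve(diag(n) + lambda * crossprod(D), y))
}

# total mass of a kernel density by piecewise quadrature between kernel
# breakpoints (needed for the discontinuous compact-support kernels)
kde_mass_oracle <- function(m) {
  h <- m$bandwidth
  knots <- sort(unique(c(m$samples - h, m$samples, m$samples + h)))
  segs <- cbind(c(min(knots) - 4 * h, knots), c(knots, max(knots) + 4 * h))
  sum(apply(segs, 1, function(s) {
    stats::integrate(function(z) kde_pdf(m, z), s[1], s[2],
                     rel.tol = 1e-10)$value
  }))
}

# copula density by central finite differences of the distribution function
copula_pdf_fd_oracle <- function(spec, u, v, step = 1e-5) {
  (copula_cdf(spec, u + step, v + step) -
   copula_cdf(spec, u - step, v + step) -
   copula_cdf(spec, u + step, v - step) +
   copula_cdf(spec, u - step, v - step)) / (4 * step^2)
}

# quantile by bisection on the model's own CDF (contrast with the spline path)
kde_quantile_bisect_oracle <- function(m, p, tol = 1e-9) {
  lo <- min(m$samples) - 10 * m$bandwidth
  hi <- max(m$samples) + 10 * m$bandwidth
  vapply(p, function(pp) {
    uniroot(function(x) kde_cdf(m, x) - pp, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

# default moderate-dependence parameter per family (tau ~ 0.33)
theta_moderate <- function(family) theta_from_tau(family, 1 / 3)

copula_families <- c("normal", "gumbel", "frank", "clayton")
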