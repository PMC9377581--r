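#' Pseudo-observations for copula fitting
#'
#' Pairs of marginal-CDF-transformed data on the open unit square. Two
#' routes are provided:
#'
#' * `pseudo_obs(u, v)` wraps already-transformed probabilities;
#' * `pseudo_obs_from_kde(x, y, mx, my)` maps raw paired data through
#'   fitted [kde_model()] marginal CDFs (the default route, matching a
#'   workflow where nonparametric marginals feed the copula); and
#' * `pseudo_obs_ranks(x, y)` uses the rank transform
#'   \eqn{r_i/(n+1)}, the distribution-free alternative.
#'
#' @param u,v Probabilities strictly in (0, 1), equal length.
#' @return Object of class `pseudo_obs`: list `(u, v, n)`.
#' @export
pseudo_obs <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (any(u <= 0 | u >= 1 | v <= 0 | v >= 1))
    stop("pseudo-observations must lie strictly inside (0, 1)")
  structure(list(u = u, v = v, n = length(u)), class = "pseudo_obs")
}

#' @rdname pseudo_obs
#' @param x,y Raw paired observations.
#' @param mx,my Fitted [kde_model()] marginals for `x` and `y`.
#' @export
pseudo_obs_from_kde <- function(x, y, mx, my) {
  eps <- 1e-10
  clamp <- function(p) pmin(1 - eps, pmax(eps, p))
  pseudo_obs(clamp(kde_cdf(mx, x)), clamp(kde_cdf(my, y)))
}

#' @rdname pseudo_obs
#' @export
pseudo_obs_ranks <- function(x, y) {
  n <- length(x)
  pseudo_obs(rank(x, ties.method = "average") / (n + 1),
             rank(y, ties.method = "average") / (n + 1))
}

#' @export
print.pseudo_obs <- function(x, ...) {
  cat(sprintf("<pseudo_obs> n = %d, sample Kendall tau = %.3f\n", x$n,
              stats::cor(x$u, x$v, method = "kendall")))
  invisible(x)
}

#' Fit one copula family by maximum likelihood
#'
#' Maximises \eqn{\sum_i \log c_\theta(u_i, v_i)} over the family's
#' parameter domain by bounded one-dimensional optimisation. Boundary
#' solutions are reported as-is (a gumbel fit to negatively dependent data
#' sits at its independence boundary \eqn{\theta = 1}). The fit records the
#' implied Kendall tau, the maximised log-likelihood, an observed-information
#' standard error, and the squared Euclidean distance from the empirical
#' copula used for model selection.
#'
#' @param family Family name (see [copula_spec()]).
#' @param pobs A [pseudo_obs()] object with `n >= 10`.
#' @param bounds Optional length-2 numeric search interval overriding the
#'   family default.
#' @return Object of class `fitted_copula`: list with `spec`,
#'   `kendall_tau` (implied by theta), `sample_tau` (rank-based, from the
#'   data), `loglik`, `se`, `sq_euclid_dist`, `n`.
#' @export
fit_copula_mle <- function(family, pobs, bounds = NULL) {
  stopifnot(inherits(pobs, "pseudo_obs"))
  if (pobs$n < 10L) stop("copula MLE needs at least 10 pseudo-observations")
  family <- match.arg(family, c("normal", "gumbel", "frank", "clayton"))
  if (is.null(bounds))
    bounds <- switch(family,
      normal  = c(-0.999, 0.999),
      gumbel  = c(1, 50),
      frank   = c(-35, 35),
      clayton = c(-0.95, 50))
  nll <- function(th) {
    d <- copula_pdf(copula_spec(family, th), pobs$u, pobs$v)
    if (any(d <= 0) || any(!is.finite(d))) return(1e10)
    -sum(log(d))
  }
  opt <- stats::optimize(nll, bounds, tol = 1e-8)
  # guard against interior optima missed near the boundary (gumbel theta = 1
  # and other monotone-likelihood cases): compare with the endpoints
  cand <- c(opt$minimum, bounds)
  vals <- c(opt$objective, vapply(bounds, nll, numeric(1)))
  th <- cand[which.min(vals)]
  # snap to the gumbel independence boundary when indistinguishable
  if (family == "gumbel" && th - 1 < 1e-6) th <- 1
  if (family %in% c("frank", "clayton") && abs(th) < .indep_eps) th <- 0
  spec <- copula_spec(family, th)
  ll <- -nll(th)
  structure(list(spec = spec,
                 kendall_tau = kendall_tau_of(spec),
                 sample_tau = stats::cor(pobs$u, pobs$v, method = "kendall"),
                 loglik = ll,
                 se = mle_se(nll, th, bounds),
                 sq_euclid_dist = sq_euclid_distance(spec, pobs),
                 n = pobs$n),
            class = "fitted_copula")
}

# observed-information standard error by central second difference;
# NA at boundary optima where the quadratic approximation fails
mle_se <- function(nll, th, bounds) {
  eps <- max(1e-4, abs(th) * 1e-4)
  if (th - eps < bounds[1] || th + eps > bounds[2]) return(NA_real_)
  h <- (nll(th + eps) - 2 * nll(th) + nll(th - eps)) / eps^2
  if (!is.finite(h) || h <= 0) return(NA_real_)
  1 / sqrt(h)
}

#' @export
print.fitted_copula <- function(x, ...) {
  cat(sprintf(
    "<fitted_copula> %s: theta = %.3f, tau = %.3f, loglik = %.2f, D2 = %.4f\n",
    x$spec$family, x$spec$theta, x$kendall_tau, x$loglik, x$sq_euclid_dist))
  invisible(x)
}

#' Empirical copula
#'
#' \eqn{C_n(u, v) = n^{-1}\sum_i 1[u_i \le u,\ v_i \le v]} over the
#' pseudo-observations; the nonparametric benchmark for model selection.
#'
#' @param pobs A [pseudo_obs()].
#' @param u,v Evaluation points in \[0, 1\] (vectorized, recycled).
#' @return Probabilities.
#' @export
empirical_copula <- function(pobs, u, v) {
  stopifnot(inherits(pobs, "pseudo_obs"))
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  vapply(seq_len(n), function(i) mean(pobs$u <= u[i] & pobs$v <= v[i]),
         numeric(1))
}

#' Squared Euclidean distance from the empirical copula
#'
#' \eqn{D^2 = \sum_i [C_\theta(u_i, v_i) - C_n(u_i, v_i)]^2}, summed over
#' the pseudo-observation points themselves. Smaller is better; the
#' goodness-of-fit statistic behind [select_best()].
#'
#' @param spec A [copula_spec()].
#' @param pobs A [pseudo_obs()].
#' @return Nonnegative scalar.
#' @export
sq_euclid_distance <- function(spec, pobs) {
  stopifnot(inherits(pobs, "pseudo_obs"))
  cth <- copula_cdf(spec, pobs$u, pobs$v)
  cem <- empirical_copula(pobs, pobs$u, pobs$v)
  sum((cth - cem)^2)
}

#' Select the best-fitting copula
#'
#' Minimum squared Euclidean distance from the empirical copula; exact
#' ties broken by the fixed family order normal, frank, clayton, gumbel.
#'
#' @param fits List of [fit_copula_mle()] results.
#' @return The winning `fitted_copula`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) stop("no fitted copulas to select from")
  stopifnot(all(vapply(fits, inherits, logical(1), "fitted_copula")))
  d <- vapply(fits, function(f) f$sq_euclid_dist, numeric(1))
  fam <- vapply(fits, function(f) f$spec$family, character(1))
  pref <- match(fam, c("normal", "frank", "clayton", "gumbel"))
  fits[[order(d, pref)[1]]]
}

#' Fit all four families and select
#'
#' Convenience wrapper: [fit_copula_mle()] for normal, gumbel, frank and
#' clayton on the same pseudo-observations, returning every fit plus the
#' distance-selected winner.
#'
#' @param pobs A [pseudo_obs()].
#' @return List with `fits` (named list of `fitted_copula`) and `best`.
#' @export
fit_all_families <- function(pobs) {
  fams <- c("normal", "gumbel", "frank", "clayton")
  fits <- lapply(fams, fit_copula_mle, pobs = pobs)
  names(fits) <- fams
  list(fits = fits, best = select_best(fits))
}
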