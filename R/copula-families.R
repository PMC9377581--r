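#' Bivariate copula specification
#'
#' The four families used for yield-stressor dependence modelling:
#'
#' * `normal` (Gaussian): \eqn{C(u,v)} is the bivariate standard normal
#'   rectangle probability with correlation \eqn{\theta \in (-1, 1)}.
#' * `gumbel`: \eqn{C(u,v) = \exp\{-[(-\ln u)^\theta +
#'   (-\ln v)^\theta]^{1/\theta}\}}, \eqn{\theta \ge 1} (upper tail
#'   dependence, positive dependence only; \eqn{\theta = 1} is independence).
#' * `frank`: \eqn{C(u,v) = -\theta^{-1}\ln[1 + (e^{-\theta u}-1)
#'   (e^{-\theta v}-1)/(e^{-\theta}-1)]}, \eqn{\theta \ne 0}, symmetric,
#'   both signs of dependence.
#' * `clayton`: \eqn{C(u,v) = \max(u^{-\theta}+v^{-\theta}-1, 0)^{-1/\theta}},
#'   \eqn{\theta \in [-1,\infty)\setminus\{0\}} (lower tail dependence for
#'   \eqn{\theta > 0}).
#'
#' For frank and clayton, \eqn{|\theta| < 10^{-6}} is treated as the
#' independence copula to avoid 0/0 in the formulas.
#'
#' @param family One of `"normal"`, `"gumbel"`, `"frank"`, `"clayton"`.
#' @param theta Dependence parameter in the family's domain.
#' @return Object of class `copula_spec`: list `(family, theta)`.
#' @examples
#' copula_spec("clayton", 2)
#' copula_cdf(copula_spec("clayton", 2), 0.5, 0.5)  # 7^(-1/2)
#' @export
copula_spec <- function(family = c("normal", "gumbel", "frank", "clayton"),
                        theta) {
  family <- match.arg(family)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("`theta` must be a single finite number")
  ok <- switch(family,
    normal  = theta > -1 && theta < 1,
    gumbel  = theta >= 1,
    frank   = TRUE,           # theta ~ 0 treated as independence
    clayton = theta >= -1)
  if (!ok)
    stop(sprintf("theta = %g outside the %s family's domain", theta, family))
  structure(list(family = family, theta = theta), class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("<copula_spec> %s, theta = %.4g (Kendall tau %.3f)\n",
              x$family, x$theta, kendall_tau_of(x)))
  invisible(x)
}

.indep_eps <- 1e-6
is_indep <- function(spec) {
  switch(spec$family,
         normal  = abs(spec$theta) < .indep_eps,
         gumbel  = spec$theta - 1 < .indep_eps,
         frank   = abs(spec$theta) < .indep_eps,
         clayton = abs(spec$theta) < .indep_eps)
}

#' Copula distribution function
#'
#' Evaluates \eqn{C(u, v)} for the given family. The Gaussian family's
#' rectangle probability is computed by adaptive quadrature of the
#' conditional-normal representation
#' \eqn{C(u,v) = \int_{-\infty}^{\Phi^{-1}(u)}
#' \phi(s)\,\Phi\!\big((\Phi^{-1}(v)-\theta s)/\sqrt{1-\theta^2}\big)\,ds}
#' to absolute tolerance 1e-10.
#'
#' @param spec A [copula_spec()].
#' @param u,v Probabilities in \[0, 1\]; vectorized (recycled to a common
#'   length).
#' @return \eqn{C(u,v)} with uniform margins: `C(u,1) = u`, `C(u,0) = 0`.
#' @export
copula_cdf <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  if (any(u < 0 | u > 1 | v < 0 | v > 1))
    stop("u and v must lie in [0, 1]")
  if (is_indep(spec)) return(u * v)
  th <- spec$theta
  out <- switch(spec$family,
    normal = mapply(normal_copula_cdf1, u, v, MoreArgs = list(rho = th)),
    gumbel = {
      res <- numeric(n)
      inner <- u > 0 & v > 0
      a <- (-log(u[inner]))^th; b <- (-log(v[inner]))^th
      res[inner] <- exp(-(a + b)^(1 / th))
      res
    },
    frank = -log1p(expm1(-th * u) * expm1(-th * v) / expm1(-th)) / th,
    clayton = {
      if (th > 0) {
        res <- numeric(n)
        inner <- u > 0 & v > 0
        res[inner] <- (u[inner]^(-th) + v[inner]^(-th) - 1)^(-1 / th)
        res
      } else {
        s <- pmax(u^(-th) + v^(-th) - 1, 0)
        ifelse(s > 0, s^(-1 / th), 0)
      }
    })
  # clamp away round-off excursions outside the Frechet bounds
  pmin(pmax(out, 0), pmin(u, v))
}

normal_copula_cdf1 <- function(u, v, rho) {
  if (u <= 0 || v <= 0) return(0)
  if (u >= 1) return(v)
  if (v >= 1) return(u)
  x <- stats::qnorm(u); y <- stats::qnorm(v)
  s <- sqrt(1 - rho^2)
  stats::integrate(function(t) stats::dnorm(t) * stats::pnorm((y - rho * t) / s),
                   -Inf, x, abs.tol = 1e-10, rel.tol = 1e-10)$value
}

#' Copula density
#'
#' The mixed partial derivative \eqn{c(u,v) = \partial^2 C/\partial u
#' \partial v}, evaluated analytically for each family on the open unit
#' square.
#'
#' @inheritParams copula_cdf
#' @return Nonnegative density values; the independence limits give
#'   \eqn{c \equiv 1}.
#' @export
copula_pdf <- function(spec, u, v) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  if (any(u <= 0 | u >= 1 | v <= 0 | v >= 1))
    stop("copula density is evaluated on the open unit square (0,1)^2")
  if (is_indep(spec)) return(rep(1, n))
  th <- spec$theta
  switch(spec$family,
    normal = {
      x <- stats::qnorm(u); y <- stats::qnorm(v)
      s2 <- 1 - th^2
      exp(-(th^2 * (x^2 + y^2) - 2 * th * x * y) / (2 * s2)) / sqrt(s2)
    },
    gumbel = {
      a <- -log(u); b <- -log(v)
      S <- a^th + b^th
      A <- S^(1 / th)
      exp(-A) / (u * v) * (a * b)^(th - 1) * S^(1 / th - 2) *
        (A + th - 1)
    },
    frank = {
      num <- th * (1 - exp(-th)) * exp(-th * (u + v))
      den <- ((1 - exp(-th)) - (1 - exp(-th * u)) * (1 - exp(-th * v)))^2
      num / den
    },
    clayton = {
      s <- u^(-th) + v^(-th) - 1
      ifelse(s > 0,
             (1 + th) * (u * v)^(-th - 1) * s^(-1 / th - 2),
             0)
    })
}

#' Kendall's tau implied by a copula parameter
#'
#' Closed-form concordance maps: normal
#' \eqn{\tau = (2/\pi)\arcsin\theta}; clayton \eqn{\tau = \theta/(\theta+2)};
#' gumbel \eqn{\tau = 1 - 1/\theta}; frank
#' \eqn{\tau = 1 + 4(D_1(\theta) - 1)/\theta} with \eqn{D_1} the first
#' Debye function (evaluated by adaptive quadrature; the map is odd in
#' \eqn{\theta}).
#'
#' @param spec A [copula_spec()], or a family name if `theta` is supplied.
#' @param theta Optional parameter when `spec` is a family name.
#' @return Kendall's tau in \[-1, 1\].
#' @examples
#' kendall_tau_of(copula_spec("clayton", 0.453))  # 0.185
#' @export
kendall_tau_of <- function(spec, theta = NULL) {
  if (is.character(spec)) spec <- copula_spec(spec, theta)
  stopifnot(inherits(spec, "copula_spec"))
  th <- spec$theta
  switch(spec$family,
    normal  = 2 / pi * asin(th),
    clayton = th / (th + 2),
    gumbel  = 1 - 1 / th,
    frank   = {
      if (abs(th) < .indep_eps) 0
      else sign(th) * (1 + 4 * (debye1(abs(th)) - 1) / abs(th))
    })
}

# first Debye function D1(x) = (1/x) int_0^x t/(e^t - 1) dt, x > 0
debye1 <- function(x) {
  stopifnot(x > 0)
  stats::integrate(function(t) ifelse(t == 0, 1, t / expm1(t)), 0, x,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value / x
}

#' Copula parameter implied by Kendall's tau
#'
#' Inverse of [kendall_tau_of()]; used to parameterize synthetic scenarios
#' by dependence strength. The frank inversion is numeric (monotone
#' root-finding); gumbel and clayton require `tau >= 0`.
#'
#' @param family Family name.
#' @param tau Kendall's tau.
#' @return The parameter theta.
#' @export
theta_from_tau <- function(family = c("normal", "gumbel", "frank", "clayton"),
                           tau) {
  family <- match.arg(family)
  stopifnot(is.numeric(tau), length(tau) == 1L, abs(tau) < 1)
  switch(family,
    normal = sin(pi * tau / 2),
    gumbel = {
      if (tau < 0) stop("gumbel copula cannot express negative dependence")
      1 / (1 - tau)
    },
    clayton = {
      if (tau < 0) stop("use a frank or normal copula for negative tau")
      if (tau == 0) 0 else 2 * tau / (1 - tau)
    },
    frank = {
      if (abs(tau) < 1e-10) return(0)
      f <- function(th) kendall_tau_of(copula_spec("frank", th)) - abs(tau)
      r <- stats::uniroot(f, c(1e-5, 500), tol = 1e-12)$root
      sign(tau) * r
    })
}

#' Conditional distribution (h-function) and its inverse
#'
#' `copula_hfun` evaluates \eqn{h(v \mid u) = \partial C(u,v)/\partial u},
#' the conditional CDF of `v` given `u`; `copula_hinv` solves
#' \eqn{h(v \mid u) = w} for `v`. Conditional inversion is the sampling
#' mechanism: with `u, w` i.i.d. uniform, `(u, hinv(w, u))` is a draw from
#' the copula. Normal, frank and clayton invert in closed form; gumbel is
#' inverted numerically by monotone root-finding (tolerance 1e-10).
#'
#' @param spec A [copula_spec()].
#' @param v,u,w Vectors in (0, 1).
#' @return Probabilities in (0, 1).
#' @export
copula_hfun <- function(spec, v, u) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  if (is_indep(spec)) return(v)
  th <- spec$theta
  switch(spec$family,
    normal = {
      x <- stats::qnorm(u); y <- stats::qnorm(v)
      stats::pnorm((y - th * x) / sqrt(1 - th^2))
    },
    gumbel = {
      a <- -log(u); b <- -log(v)
      S <- a^th + b^th
      exp(-S^(1 / th)) * a^(th - 1) * S^(1 / th - 1) / u
    },
    frank = {
      eu <- expm1(-th * u); ev <- expm1(-th * v)
      (eu + 1) * ev / (expm1(-th) + eu * ev)
    },
    clayton = {
      s <- u^(-th) + v^(-th) - 1
      ifelse(s > 0, u^(-th - 1) * s^(-1 / th - 1), as.numeric(th < 0))
    })
}

#' @rdname copula_hfun
#' @export
copula_hinv <- function(spec, w, u) {
  stopifnot(inherits(spec, "copula_spec"))
  n <- max(length(u), length(w))
  u <- rep_len(u, n); w <- rep_len(w, n)
  if (any(u <= 0 | u >= 1 | w <= 0 | w >= 1))
    stop("u and w must lie strictly in (0, 1)")
  if (is_indep(spec)) return(w)
  th <- spec$theta
  switch(spec$family,
    normal = stats::pnorm(sqrt(1 - th^2) * stats::qnorm(w) +
                          th * stats::qnorm(u)),
    frank = {
      t <- w * expm1(-th) / (exp(-th * u) - w * expm1(-th * u))
      -log1p(t) / th
    },
    clayton = {
      base <- u^(-th) * (w^(-th / (1 + th)) - 1) + 1
      pmin(1 - 1e-15, pmax(base, 1e-300)^(-1 / th))
    },
    gumbel = vapply(seq_len(n), function(i) {
      gumbel_hinv1(th, w[i], u[i])
    }, numeric(1)))
}

gumbel_hinv1 <- function(th, w, u) {
  f <- function(v) copula_hfun(copula_spec("gumbel", th), v, u) - w
  lo <- 1e-12; hi <- 1 - 1e-12
  # h(v|u) is increasing in v from 0 to 1
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Sample from a bivariate copula
#'
#' Draws `n` i.i.d. pairs by conditional inversion (see [copula_hinv()]):
#' both coordinates are uniform on (0, 1) with the family's dependence.
#'
#' @param spec A [copula_spec()].
#' @param n Number of draws.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Object of class `pseudo_obs`: list with vectors `u`, `v` and
#'   size `n`.
#' @examples
#' p <- copula_sample(copula_spec("clayton", 2), 500, seed = 1)
#' cor(p$u, p$v, method = "kendall")  # near theta/(theta+2) = 0.5
#' @export
copula_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  w <- stats::runif(n)
  v <- copula_hinv(spec, w, u)
  pseudo_obs(u, v)
}
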