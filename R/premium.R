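#' Monte-Carlo rating configuration
#'
#' Settings for the premium simulation: number of Monte-Carlo draws
#' (default 10,000), the coverage-level grid (70% to 100% in 5% steps),
#' the expected yield \eqn{\bar y} used as the indemnity anchor, and the
#' RNG seed.
#'
#' @param expected_yield Positive expected yield level \eqn{\bar y}
#'   (tonnes, or normalized units).
#' @param n_sim Number of Monte-Carlo draws, at least 100.
#' @param coverage_grid Ascending coverage levels \eqn{\alpha \in [0,1]}.
#' @param seed Optional integer seed for the simulation.
#' @param denominator `"alpha_ybar"` (default) rates losses against the
#'   insured liability \eqn{\alpha\bar y}; `"ybar"` rates against
#'   \eqn{\bar y}.
#' @return Object of class `rating_config`.
#' @export
rating_config <- function(expected_yield, n_sim = 10000L,
                          coverage_grid = seq(0.70, 1.00, by = 0.05),
                          seed = NULL,
                          denominator = c("alpha_ybar", "ybar")) {
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(expected_yield), length(expected_yield) == 1L,
            expected_yield > 0)
  if (n_sim < 100L) stop("n_sim must be at least 100")
  coverage_grid <- as.numeric(coverage_grid)
  if (is.unsorted(coverage_grid) || any(coverage_grid < 0 | coverage_grid > 1))
    stop("coverage_grid must be ascending within [0, 1]")
  structure(list(expected_yield = expected_yield, n_sim = as.integer(n_sim),
                 coverage_grid = coverage_grid, seed = seed,
                 denominator = denominator),
            class = "rating_config")
}

#' Simulate joint yield/stressor draws from the fitted model
#'
#' Draws `n_sim` dependent uniform pairs from the selected copula and maps
#' them through the inverse marginal CDFs ("reduction processing"): the
#' first coordinate through the yield marginal, the second through the
#' stressor (SST or SSS extreme) marginal. The yield sample inherits the
#' yield marginal exactly; the dependence with the stressor is the
#' copula's.
#'
#' @param copula A [fit_copula_mle()] result or a [copula_spec()].
#' @param yield_marginal,stressor_marginal Fitted [kde_model()] objects.
#' @param cfg A [rating_config()].
#' @return A data frame with columns `yield` and `stressor`, `n_sim` rows.
#' @export
simulate_yields <- function(copula, yield_marginal, stressor_marginal, cfg) {
  spec <- if (inherits(copula, "fitted_copula")) copula$spec else copula
  stopifnot(inherits(spec, "copula_spec"),
            inherits(yield_marginal, "kde_model"),
            inherits(stressor_marginal, "kde_model"),
            inherits(cfg, "rating_config"))
  p <- copula_sample(spec, cfg$n_sim, seed = cfg$seed)
  data.frame(yield = kde_quantile(yield_marginal, p$u),
             stressor = kde_quantile(stressor_marginal, p$v))
}

#' Expected indemnified loss at a coverage level
#'
#' Sample estimate of
#' \eqn{P(y < \alpha\bar y)\,[\alpha\bar y - E(y \mid y < \alpha\bar y)]},
#' i.e. the mean shortfall \eqn{E(\alpha\bar y - y)^+}: zero when no
#' simulated yield falls below the trigger \eqn{\alpha\bar y}.
#'
#' @param yields Numeric vector of (simulated) yields.
#' @param alpha Coverage level in \[0, 1\].
#' @param ybar Expected yield \eqn{\bar y > 0}.
#' @return Nonnegative expected loss (yield units).
#' @export
expected_loss <- function(yields, alpha, ybar) {
  if (length(yields) == 0L) stop("empty yield sample")
  stopifnot(alpha >= 0, alpha <= 1, ybar > 0)
  mean(pmax(alpha * ybar - yields, 0))
}

#' Pure premium rate
#'
#' \eqn{r = E[\text{loss}] / (\alpha\bar y)}: expected indemnity per unit
#' of insured liability (the actuarially fair rate before loading). With
#' `denominator = "ybar"` the loss is rated against \eqn{\bar y} instead.
#'
#' @param loss Nonnegative expected loss.
#' @param alpha Coverage level, strictly positive.
#' @param ybar Expected yield.
#' @param denominator See [rating_config()].
#' @return Rate in \[0, 1\] whenever yields are nonnegative.
#' @export
premium_rate <- function(loss, alpha, ybar,
                         denominator = c("alpha_ybar", "ybar")) {
  denominator <- match.arg(denominator)
  stopifnot(loss >= 0, ybar > 0)
  if (alpha <= 0) stop("premium rate undefined at alpha = 0 (zero liability)")
  loss / (if (denominator == "alpha_ybar") alpha * ybar else ybar)
}

#' Premium schedule across coverage levels
#'
#' Runs one shared Monte-Carlo simulation (so the schedule is exactly
#' monotone in \eqn{\alpha} within a run) and evaluates the expected loss,
#' pure rate and Monte-Carlo standard error at every coverage level in the
#' grid.
#'
#' @inheritParams simulate_yields
#' @return Object of class `premium_schedule`: a data frame with columns
#'   `alpha`, `expected_loss`, `rate`, `mc_stderr`, plus attributes
#'   `expected_yield`, `n_sim`, `denominator`, `copula_family`.
#' @examples
#' yk <- kde_model(rnorm(19, 100, 15))
#' sk <- kde_model(rnorm(19, 15, 2))
#' cfg <- rating_config(expected_yield = 100, n_sim = 2000, seed = 7)
#' coverage_sweep(copula_spec("clayton", 0.5), yk, sk, cfg)
#' @export
coverage_sweep <- function(copula, yield_marginal, stressor_marginal, cfg) {
  sims <- simulate_yields(copula, yield_marginal, stressor_marginal, cfg)
  schedule_from_sample(sims$yield, cfg,
                       family = if (inherits(copula, "fitted_copula"))
                         copula$spec$family else copula$family)
}

# rate schedule from an already-simulated yield sample
schedule_from_sample <- function(yields, cfg, family = NA_character_) {
  ybar <- cfg$expected_yield
  rows <- lapply(cfg$coverage_grid, function(a) {
    if (a == 0)
      return(data.frame(alpha = a, expected_loss = 0, rate = 0, mc_stderr = 0))
    short <- pmax(a * ybar - yields, 0)
    loss <- mean(short)
    denom <- if (cfg$denominator == "alpha_ybar") a * ybar else ybar
    data.frame(alpha = a, expected_loss = loss, rate = loss / denom,
               mc_stderr = stats::sd(short) / sqrt(length(short)) / denom)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("premium_schedule", "data.frame"),
            expected_yield = ybar, n_sim = length(yields),
            denominator = cfg$denominator, copula_family = family)
}

#' @export
print.premium_schedule <- function(x, digits = 2, ...) {
  cat(sprintf(
    "<premium_schedule> ybar = %.4g, n_sim = %d, copula = %s\n",
    attr(x, "expected_yield"), attr(x, "n_sim"), attr(x, "copula_family")))
  df <- data.frame(coverage = sprintf("%.0f%%", 100 * x$alpha),
                   rate = sprintf(paste0("%.", digits, "f%%"), 100 * x$rate),
                   mc_stderr = sprintf("%.3f%%", 100 * x$mc_stderr))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Quadrature rate oracle for a kernel marginal
#'
#' Computes the expected shortfall \eqn{E(\alpha\bar y - y)^+} by direct
#' numeric integration of the marginal density (no simulation); used as an
#' independent check of the Monte-Carlo schedule.
#'
#' @param yield_marginal A [kde_model()].
#' @param alpha Coverage level.
#' @param ybar Expected yield.
#' @param denominator See [rating_config()].
#' @return The rate.
#' @export
quadrature_rate <- function(yield_marginal, alpha, ybar,
                            denominator = c("alpha_ybar", "ybar")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(yield_marginal, "kde_model"), alpha > 0, ybar > 0)
  lo <- min(yield_marginal$samples) - 10 * yield_marginal$bandwidth
  trigger <- alpha * ybar
  loss <- if (trigger <= lo) 0 else
    stats::integrate(function(y) (trigger - y) * kde_pdf(yield_marginal, y),
                     lo, trigger, rel.tol = 1e-9,
                     subdivisions = 500L)$value
  loss / (if (denominator == "alpha_ybar") trigger else ybar)
}
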