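#' Hodrick-Prescott trend/fluctuation decomposition
#'
#' Splits an annual series \eqn{y_t} into a smooth trend \eqn{g_t} and a
#' fluctuation \eqn{c_t = y_t - g_t} by minimising
#' \deqn{\sum_t (y_t - g_t)^2 + \lambda \sum_t [(g_{t+1}-g_t)-(g_t-g_{t-1})]^2,}
#' the usual penalised least-squares trend filter. The first-order condition
#' is the linear system \eqn{(I + \lambda D^\top D) g = y} with \eqn{D} the
#' second-difference operator, solved directly (the series here are short
#' annual panels, so a dense solve is exact and cheap).
#'
#' For yield series the conventional smoothing weight for annual data is
#' `lambda = 100`. `lambda = 0` returns the series itself as trend; as
#' `lambda` grows the trend approaches the least-squares straight line.
#'
#' @param series An [annual_series()] (or plain numeric vector) of length >= 5.
#' @param lambda Non-negative smoothing parameter; default 100 (annual data).
#'
#' @return An object of class `hp_decomposition`: list with `trend`,
#'   `fluctuation` (both numeric, same length as input), `lambda`, `years`,
#'   `label`, `units`, and `values` (the input).
#' @examples
#' s <- annual_series(c(10, 12, 15, 14, 18, 21, 20), 2001:2007)
#' d <- hp_filter(s, lambda = 100)
#' all.equal(d$trend + d$fluctuation, s$values)
#' @export
hp_filter <- function(series, lambda = 100) {
  series <- as_annual_series(series)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop("`lambda` must be a single finite non-negative number")
  y <- series$values
  n <- length(y)
  if (lambda == 0) {
    g <- y
  } else {
    D <- second_difference_matrix(n)
    A <- diag(n) + lambda * crossprod(D)
    g <- as.numeric(solve(A, y))
  }
  structure(list(trend = g, fluctuation = y - g, lambda = lambda,
                 years = series$years, label = series$label,
                 units = series$units, values = y),
            class = "hp_decomposition")
}

# (n-2) x n second-difference operator: (Dg)_t = g_{t+2} - 2 g_{t+1} + g_t
second_difference_matrix <- function(n) {
  stopifnot(n >= 3L)
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i + 0:2] <- c(1, -2, 1)
  D
}

#' @export
print.hp_decomposition <- function(x, ...) {
  cat(sprintf("<hp_decomposition> %s: n = %d, lambda = %g\n",
              x$label, length(x$values), x$lambda))
  print(data.frame(year = x$years, actual = x$values, trend = x$trend,
                   fluctuation = x$fluctuation))
  invisible(x)
}

#' Rebase a yield series to a reference year's trend level
#'
#' Removes the technological/management trend by expressing every year's
#' yield at the trend level of a base year:
#' \eqn{Y'_t = \hat Y_{base} \, Y_t / \hat Y_t}, where \eqn{\hat Y_t} is the
#' trend yield. The result is a stationary-level series in the original
#' units, comparable across years (the base period is typically the final
#' year of the panel).
#'
#' @param series The original [annual_series()].
#' @param detrend The matching [hp_filter()] decomposition.
#' @param base_year Year whose trend level anchors the rebased series;
#'   default the last year of the series.
#' @return An [annual_series()] of rebased yields `Y'_t`.
#' @export
rebase_yield <- function(series, detrend, base_year = max(series$years)) {
  series <- as_annual_series(series)
  stopifnot(inherits(detrend, "hp_decomposition"))
  if (!identical(series$years, detrend$years))
    stop("series and decomposition cover different years")
  i <- match(base_year, series$years)
  if (is.na(i)) stop("base_year ", base_year, " not present in series")
  bad <- detrend$trend <= 0
  if (any(bad))
    stop("trend is non-positive in year(s) ",
         paste(series$years[bad], collapse = ", "),
         "; rebasing requires a strictly positive trend")
  rebased <- detrend$trend[i] * series$values / detrend$trend
  annual_series(rebased, series$years,
                label = paste0(series$label, " (rebased ", base_year, ")"),
                units = series$units)
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test for short annual series, used to confirm that detrended
#' yield/SST/SSS fluctuations are stationary before any distribution fitting.
#' The test regression includes a constant,
#' \deqn{\Delta y_t = a + \rho\, y_{t-1} + \sum_{i=1}^{k} b_i \Delta y_{t-i} + e_t,}
#' with the lag order `k` chosen by AIC over `0..max_lag` (default cap
#' `floor(n/4)`, appropriate for ~19-year panels). The reported statistic is
#' the t-ratio of \eqn{\rho}. The decision compares it with fixed critical
#' values for a constant-only regression at this sample size (defaults
#' -3.872 at 1% and -3.046 at 5%); more-negative statistics reject the
#' unit root.
#'
#' @param series An [annual_series()] or numeric vector, length >= 8.
#' @param max_lag Cap on the augmentation lag order; default `floor(n/4)`.
#' @param crit Named numeric vector with elements `c1` (1% critical value)
#'   and `c5` (5%).
#' @return Object of class `adf_report`: list with `statistic`, `lag`,
#'   `crit_1pct`, `crit_5pct`, and `decision` (one of `"stationary_1pct"`,
#'   `"stationary_5pct"`, `"nonstationary"`).
#' @export
adf_test <- function(series, max_lag = NULL,
                     crit = c(c1 = -3.872, c5 = -3.046)) {
  if (inherits(series, "hp_decomposition")) {
    y <- series$fluctuation
  } else if (inherits(series, "annual_series")) {
    y <- series$values
  } else {
    y <- as.numeric(series)
  }
  n <- length(y)
  if (n < 8L) stop("ADF test needs at least 8 observations, got ", n)
  if (stats::sd(y) == 0)
    stop("series is constant; ADF regression is degenerate")
  if (is.null(max_lag)) max_lag <- max(0L, floor(n / 4))
  max_lag <- min(max_lag, n - 5L)  # keep residual df positive

  dy <- diff(y)
  ylag <- y[-n]
  # AIC comparison on the common sample trimmed to the largest lag
  aics <- vapply(0:max_lag, function(k) {
    fit <- adf_regression(dy, ylag, k, trim = max_lag)
    stats::AIC(fit)
  }, numeric(1))
  k <- (0:max_lag)[which.min(aics)]
  # refit at the chosen lag on its own maximal sample
  fit <- adf_regression(dy, ylag, k, trim = k)
  ct <- summary(fit)$coefficients
  stat <- ct["ylag0", "t value"]

  decision <- if (stat < crit[["c1"]]) "stationary_1pct"
              else if (stat < crit[["c5"]]) "stationary_5pct"
              else "nonstationary"
  structure(list(statistic = unname(stat), lag = k,
                 crit_1pct = crit[["c1"]], crit_5pct = crit[["c5"]],
                 decision = decision),
            class = "adf_report")
}

adf_regression <- function(dy, ylag, k, trim) {
  m <- length(dy)
  idx <- (trim + 1L):m
  df <- data.frame(dy = dy[idx], ylag0 = ylag[idx])
  if (k > 0L) for (i in seq_len(k)) df[[paste0("dlag", i)]] <- dy[idx - i]
  stats::lm(dy ~ ., data = df)
}

#' @export
print.adf_report <- function(x, ...) {
  cat(sprintf(
    "ADF t = %.3f (lag %d); 1%% crit %.3f, 5%% crit %.3f -> %s\n",
    x$statistic, x$lag, x$crit_1pct, x$crit_5pct, x$decision))
  invisible(x)
}

#' Dimensionless rescaling of a series
#'
#' Min-max scaling onto \[0, 1\] (the default), or z-scoring, so yield,
#' SST and SSS can be compared and density-fitted on a common dimensionless
#' scale. The affine map is returned so simulated values can be mapped back
#' to physical units.
#'
#' @param series [annual_series()] or numeric vector; must be non-constant.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return An [annual_series()] of scaled values with attribute `scaling`,
#'   a list `(method, center, scale)` such that
#'   `original = center + scale * scaled`.
#' @export
normalize_series <- function(series, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  s <- as_annual_series(series)
  x <- s$values
  if (max(x) == min(x))
    stop("cannot normalize a constant series (zero range)")
  if (method == "minmax") {
    center <- min(x); scale <- max(x) - min(x)
  } else {
    center <- mean(x); scale <- stats::sd(x)
  }
  out <- annual_series((x - center) / scale, s$years,
                       label = paste0(s$label, " (normalized)"), units = "")
  attr(out, "scaling") <- list(method = method, center = center, scale = scale)
  out
}

#' Invert [normalize_series()]
#'
#' @param x Numeric vector on the normalized scale.
#' @param scaling The `scaling` attribute of a normalized series.
#' @return Numeric vector on the original scale.
#' @export
denormalize <- function(x, scaling) scaling$center + scaling$scale * x

#' Sample skewness and kurtosis
#'
#' Moment-based shape statistics of a series: skewness \eqn{m_3/m_2^{3/2}}
#' and Pearson kurtosis \eqn{m_4/m_2^2} (so a normal sample has kurtosis 3;
#' values below 3 indicate the "low peak, thin tail" shape).
#'
#' @param series [annual_series()] or numeric vector, length >= 4.
#' @return Named numeric vector `c(skewness = , kurtosis = )`.
#' @export
shape_stats <- function(series) {
  x <- if (inherits(series, "annual_series")) series$values else
       as.numeric(series)
  if (length(x) < 4L) stop("shape statistics need at least 4 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance; shape statistics undefined")
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}
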