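#' Synthetic scenario specification
#'
#' Defines a city-like ground-truth scenario: a smooth multi-year yield
#' trend, marginal distributions for the yield fluctuation and for the two
#' annual environmental extremes (minimum SST over the stress window,
#' maximum SSS), and a copula per yield-stressor pair. Panels generated
#' from a scenario have known dependence structure, so fitting and rating
#' can be validated end to end.
#'
#' Defaults emulate a 19-year coastal aquaculture panel (2001-2019): a
#' linear technology trend around 8,000-11,000 tonnes; yield fluctuations
#' of a few hundred tonnes; winter SST minima centred near the 15 degC
#' cold-stress threshold with a multi-year range of about 3 degC; SSS
#' maxima spanning the observed coastal range 28.2-35.7 per-mille. The
#' default dependence is a positive clayton copula with SST minima (cold
#' winters depress yield) and a negative frank copula with SSS maxima
#' (hypersaline years depress yield), with magnitudes typical of fitted
#' coastal panels (|tau| roughly 0.2).
#'
#' @param n_years Panel length in years (>= 8); default 19.
#' @param start_year First year; default 2001.
#' @param trend List: `type` (`"linear"` or `"quadratic"`) and
#'   coefficients `base`, `slope` (and `quad` for quadratic), in tonnes.
#' @param yield_marginal,sst_marginal,sss_marginal Marginal specs: either
#'   `list(dist = "normal", mean =, sd =)` or
#'   `list(dist = "scaled_beta", shape1 =, shape2 =, min =, max =)`.
#' @param copula_sst,copula_sss [copula_spec()] for the yield-SST and
#'   yield-SSS pairs.
#' @param noise_sd Extra i.i.d. yield noise (tonnes) on top of the
#'   copula-linked fluctuation; default 0 so the generated dependence is
#'   exactly the specified copula.
#' @param seed Integer seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_years = 19L, start_year = 2001L,
                          trend = list(type = "linear", base = 8000,
                                       slope = 150),
                          yield_marginal = list(dist = "normal", mean = 0,
                                                sd = 600),
                          sst_marginal = list(dist = "scaled_beta",
                                              shape1 = 2, shape2 = 2,
                                              min = 13.4, max = 16.6),
                          sss_marginal = list(dist = "scaled_beta",
                                              shape1 = 2, shape2 = 2,
                                              min = 28.16, max = 35.71),
                          copula_sst = copula_spec("clayton", 0.5),
                          copula_sss = copula_spec("frank", -2.4),
                          noise_sd = 0, seed = 1L) {
  if (n_years < 8L) stop("scenarios need n_years >= 8")
  stopifnot(inherits(copula_sst, "copula_spec"),
            inherits(copula_sss, "copula_spec"),
            noise_sd >= 0)
  for (m in list(sst_marginal, sss_marginal)) marginal_quantile(m)  # validate
  marginal_quantile(yield_marginal)
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year), trend = trend,
                 yield_marginal = yield_marginal,
                 sst_marginal = sst_marginal, sss_marginal = sss_marginal,
                 copula_sst = copula_sst, copula_sss = copula_sss,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario_spec")
}

# quantile function for a named marginal spec
marginal_quantile <- function(m) {
  if (!is.list(m) || is.null(m$dist))
    stop("marginal spec must be a list with a `dist` element")
  switch(m$dist,
    normal = {
      stopifnot(is.numeric(m$mean), is.numeric(m$sd), m$sd > 0)
      function(p) stats::qnorm(p, m$mean, m$sd)
    },
    scaled_beta = {
      stopifnot(is.numeric(m$shape1), is.numeric(m$shape2), m$max > m$min)
      function(p) m$min + (m$max - m$min) * stats::qbeta(p, m$shape1, m$shape2)
    },
    stop("unknown marginal distribution: ", m$dist))
}

trend_values <- function(trend, n) {
  t0 <- seq_len(n) - 1
  switch(trend$type,
    linear = trend$base + trend$slope * t0,
    quadratic = trend$base + trend$slope * t0 +
      (trend$quad %||% 0) * t0^2,
    stop("unknown trend type: ", trend$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic annual panel with known ground truth
#'
#' Draws one dependent uniform per year for the yield fluctuation and maps
#' it to each stressor through the pair's copula by conditional inversion,
#' so the yield-SST and yield-SSS dependence each equal the specified
#' copulas exactly (when `noise_sd = 0`). The yield fluctuation and
#' stressor extremes are then pushed through the scenario marginals and
#' the trend added to yield.
#'
#' @param spec A [scenario_spec()].
#' @return List with [annual_series()] elements `yield`, `sst_extreme`,
#'   `sss_extreme`, and `truth` (the generating spec plus the latent
#'   uniforms and the trend).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_years
  years <- spec$start_year + seq_len(n) - 1L
  eps <- 1e-9
  clamp <- function(p) pmin(1 - eps, pmax(eps, p))
  u <- clamp(stats::runif(n))
  v_sst <- copula_hinv(spec$copula_sst, clamp(stats::runif(n)), u)
  v_sss <- copula_hinv(spec$copula_sss, clamp(stats::runif(n)), u)
  g <- trend_values(spec$trend, n)
  fluct <- marginal_quantile(spec$yield_marginal)(u)
  if (spec$noise_sd > 0) fluct <- fluct + stats::rnorm(n, 0, spec$noise_sd)
  list(
    yield = annual_series(g + fluct, years, label = "synthetic yield",
                          units = "tonnes"),
    sst_extreme = annual_series(marginal_quantile(spec$sst_marginal)(v_sst),
                                years, label = "synthetic SST minimum",
                                units = "degC"),
    sss_extreme = annual_series(marginal_quantile(spec$sss_marginal)(v_sss),
                                years, label = "synthetic SSS maximum",
                                units = "permille"),
    truth = list(spec = spec, u = u, v_sst = v_sst, v_sss = v_sss,
                 trend = g))
}

#' Default stress windows
#'
#' The commercial-crab cycle splits into a growth period (June-November)
#' and a breeding period (November-February). Extremes are pooled over
#' June-February by default; windows crossing the calendar boundary are
#' attributed to the starting (November-side) year.
#'
#' @return Named list of windows, each `list(start = "mm-dd", end = "mm-dd")`.
#' @export
stage_windows <- function() {
  list(pooled = list(start = "06-01", end = "02-28"),
       growth = list(start = "06-01", end = "11-30"),
       breeding = list(start = "11-01", end = "02-28"))
}

#' Generate 3-day SST/SSS series consistent with a panel
#'
#' Builds seasonal sinusoid-plus-noise series at 3-day resolution (about
#' 122 points per year) covering the panel years plus the tail of the last
#' stress window, then offsets each year's in-window segment by a constant
#' so the within-window minimum SST and maximum SSS equal the panel's
#' annual extremes exactly. SST troughs in late January and SSS peaks in
#' August, so both extremes fall naturally inside the pooled June-February
#' window.
#'
#' @param spec A [scenario_spec()].
#' @param panel Output of [generate_panel()]; regenerated from `spec` if
#'   missing.
#' @param window A window from [stage_windows()]; default pooled.
#' @return List of two data frames `sst` and `sss` with columns `date`,
#'   `value`.
#' @export
generate_threeday_series <- function(spec, panel = generate_panel(spec),
                                     window = stage_windows()$pooled) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(window$start) || is.null(window$end))
    stop("window must have `start` and `end` mm-dd elements")
  years <- panel$yield$years
  set.seed(spec$seed + 777L)
  d0 <- as.Date(sprintf("%d-01-01", min(years)))
  d1 <- as.Date(sprintf("%d-03-01", max(years) + 1L))
  dates <- seq(d0, d1, by = 3L)
  doy <- as.numeric(format(dates, "%j"))
  sst <- 20 + 9 * cos(2 * pi * (doy - 213) / 365.25) +
    stats::rnorm(length(dates), 0, 0.5)
  sss <- 31 + 2 * cos(2 * pi * (doy - 225) / 365.25) +
    stats::rnorm(length(dates), 0, 0.3)
  for (i in seq_along(years)) {
    y <- years[i]
    win <- which(in_window(dates, y, window))
    if (length(win) == 0L) stop("empty stress window for year ", y)
    # shift the whole window-to-window cycle by one constant so the series
    # stays continuous inside the year and off-window spring points cannot
    # undercut the matched winter extreme
    cyc <- which(dates >= as.Date(sprintf("%d-%s", y, window$start)) &
                 dates < as.Date(sprintf("%d-%s", y + 1L, window$start)))
    sst[cyc] <- sst[cyc] + (panel$sst_extreme$values[i] - min(sst[win]))
    sss[cyc] <- sss[cyc] + (panel$sss_extreme$values[i] - max(sss[win]))
  }
  list(sst = data.frame(date = dates, value = sst),
       sss = data.frame(date = dates, value = sss))
}

# logical index of dates inside year `y`'s window; windows whose end
# month-day precedes their start cross the calendar boundary into y + 1
in_window <- function(dates, y, window) {
  crosses <- window$end < window$start  # "02-28" < "06-01" lexically
  start <- as.Date(sprintf("%d-%s", y, window$start))
  end <- as.Date(sprintf("%d-%s", if (crosses) y + 1L else y, window$end))
  dates >= start & dates <= end
}

#' Annual extreme over a stress window
#'
#' Per-year minimum (SST) or maximum (SSS) of a 3-day series over the
#' stress window; windows spanning the year boundary are attributed to the
#' starting year.
#'
#' @param series Data frame with columns `date` (Date) and `value`.
#' @param window `list(start = "mm-dd", end = "mm-dd")`.
#' @param kind `"min"` or `"max"`.
#' @param years Years to extract; default every year whose window is fully
#'   covered by the series' date range.
#' @param label,units Passed to [annual_series()].
#' @return An [annual_series()] of extremes.
#' @export
annual_extreme <- function(series, window, kind = c("min", "max"),
                           years = NULL, label = "", units = "") {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(series), all(c("date", "value") %in% names(series)))
  dates <- as.Date(series$date)
  if (is.null(years)) {
    crosses <- window$end < window$start
    cand <- sort(unique(as.integer(format(dates, "%Y"))))
    years <- Filter(function(y) {
      s <- as.Date(sprintf("%d-%s", y, window$start))
      e <- as.Date(sprintf("%d-%s", if (crosses) y + 1L else y, window$end))
      s >= min(dates) && e <= max(dates)
    }, cand)
  }
  if (length(years) == 0L) stop("no year has full window coverage")
  vals <- vapply(years, function(y) {
    w <- series$value[in_window(dates, y, window)]
    if (length(w) == 0L) return(NA_real_)
    if (kind == "min") min(w) else max(w)
  }, numeric(1))
  if (anyNA(vals))
    stop("no series coverage in the window for year(s) ",
         paste(years[is.na(vals)], collapse = ", "))
  annual_series(vals, years, label = label, units = units)
}

#' Write a synthetic scenario as pipeline CSV inputs
#'
#' Materialises a scenario as the three long-format CSV files
#' (`city, year, value`) that [run_all()] reads, one file per variable,
#' with one block per requested city (each city gets its own derived
#' seed).
#'
#' @param spec A [scenario_spec()] template.
#' @param cities Character vector of city names.
#' @param dir Output directory (created if needed).
#' @param master_seed Seed combined with each city name (see
#'   [city_seed()]).
#' @return Invisibly, the paths of the three CSVs
#'   (`yield.csv`, `sst.csv`, `sss.csv`).
#' @export
write_synthetic_inputs <- function(spec, cities, dir,
                                   master_seed = spec$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cities, function(city) {
    s <- spec
    s$seed <- city_seed(master_seed, city)
    p <- generate_panel(s)
    list(yield = data.frame(city = city, year = p$yield$years,
                            value = p$yield$values),
         sst = data.frame(city = city, year = p$sst_extreme$years,
                          value = p$sst_extreme$values),
         sss = data.frame(city = city, year = p$sss_extreme$years,
                          value = p$sss_extreme$values))
  })
  paths <- c(yield = file.path(dir, "yield.csv"),
             sst = file.path(dir, "sst.csv"),
             sss = file.path(dir, "sss.csv"))
  for (v in names(paths))
    utils::write.csv(do.call(rbind, lapply(rows, `[[`, v)), paths[[v]],
                     row.names = FALSE)
  invisible(paths)
}
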