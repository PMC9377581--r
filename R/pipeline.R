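#' Per-city derived seed
#'
#' Stable polynomial hash of the city name mixed with the master seed, so
#' every city's simulation stream is reproducible and independent of which
#' other cities are in the batch.
#'
#' @param master Integer master seed.
#' @param city City name.
#' @return An integer seed below 2^31.
#' @export
city_seed <- function(master, city) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(city))) h <- (h * 31 + b) %% 2147483629
  as.integer((h * 7 + (as.numeric(master) %% 1e9) * 13) %% 2147483629)
}

#' Pipeline run configuration
#'
#' Collects input paths and stage parameters for the per-city analysis.
#' Can also be populated from a YAML file with [read_run_config()].
#'
#' @param yield_csv,sst_csv,sss_csv Paths to long-format CSVs with columns
#'   `city, year, value` (UTF-8, header required). The SST file holds
#'   annual within-window minima (degC), the SSS file annual maxima
#'   (per-mille).
#' @param lambda Trend-filter smoothing parameter for yield; default 100
#'   (annual data).
#' @param lambda_env Smoothing parameter for the environmental series;
#'   defaults to `lambda`.
#' @param detrend_env Detrend SST/SSS before marginal fitting (default
#'   TRUE, matching the treatment of yield).
#' @param kernel KDE kernel for all marginals; default `"gaussian"`.
#' @param normalize Fit marginals on min-max normalized series (default
#'   TRUE); simulated values are mapped back to physical units before
#'   rating either way.
#' @param pobs_method Pseudo-observation construction: `"ranks"` (the
#'   rank transform \eqn{r_i/(n+1)}, default, matching the rank-based
#'   empirical copula used for selection) or `"kde"` (marginal-CDF
#'   transform).
#' @param n_sim,coverage_grid,denominator See [rating_config()].
#' @param seed Master seed; per-city seeds derive from it via
#'   [city_seed()].
#' @param pairs Which stressor pairs to analyse: subset of
#'   `c("sss", "sst")`.
#' @param outdir Optional output directory for per-city and summary CSVs.
#' @param base_year Rebasing year; default the last overlapping year.
#' @return Object of class `run_config`.
#' @export
run_config <- function(yield_csv, sst_csv, sss_csv,
                       lambda = 100, lambda_env = lambda,
                       detrend_env = TRUE,
                       kernel = "gaussian", normalize = TRUE,
                       pobs_method = c("ranks", "kde"),
                       n_sim = 10000L,
                       coverage_grid = seq(0.70, 1.00, by = 0.05),
                       denominator = "alpha_ybar",
                       seed = 1L, pairs = c("sss", "sst"),
                       outdir = NULL, base_year = NULL) {
  pobs_method <- match.arg(pobs_method)
  pairs <- match.arg(pairs, c("sss", "sst"), several.ok = TRUE)
  for (p in c(yield_csv, sst_csv, sss_csv))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(yield_csv = yield_csv, sst_csv = sst_csv, sss_csv = sss_csv,
                 lambda = lambda, lambda_env = lambda_env,
                 detrend_env = detrend_env, kernel = kernel,
                 normalize = normalize, pobs_method = pobs_method,
                 n_sim = as.integer(n_sim), coverage_grid = coverage_grid,
                 denominator = denominator, seed = as.integer(seed),
                 pairs = pairs, outdir = outdir, base_year = base_year),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()]
#'   (paths are resolved relative to the file's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  for (k in c("yield_csv", "sst_csv", "sss_csv")) y[[k]] <- resolve(y[[k]])
  known <- names(formals(run_config))
  do.call(run_config, y[intersect(names(y), known)])
}

read_variable_csv <- function(path, variable) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("city", "year", "value")
  if ("variable" %in% names(df)) df <- df[df$variable == variable, ]
  if (!all(need %in% names(df)))
    stop(path, " must have columns city, year, value")
  df[need]
}

city_series <- function(df, city, variable, path) {
  sub <- df[df$city == city, ]
  if (nrow(sub) == 0L)
    stop("city '", city, "' missing from ", variable, " input (", path, ")")
  sub <- sub[order(sub$year), ]
  sub
}

#' Run the full analysis for one city
#'
#' Executes the complete chain: trend filtering of yield (and optionally
#' SST/SSS), rebasing to the base year, stationarity testing of the
#' detrended series, min-max normalization, kernel-density marginal
#' fitting, pseudo-observation construction, maximum-likelihood fitting of
#' all four copula families per stressor pair, distance-based selection,
#' and Monte-Carlo premium rating across the coverage grid. Rates are
#' reported on the physical yield scale with \eqn{\bar y} the mean rebased
#' yield.
#'
#' @param cfg A [run_config()].
#' @param city City name present in all three inputs with at least 8
#'   overlapping years.
#' @return Object of class `city_result`: list with elements `city`,
#'   `years`, `detrend` (per-variable [hp_filter()] results), `adf`
#'   (per-variable [adf_test()] reports), `shape` (per-variable
#'   [shape_stats()]), `marginals`, `expected_yield`, and `pairs` (per
#'   pair: `fits`, `best`, `schedule`).
#' @export
run_city <- function(cfg, city) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "read inputs"
  result <- tryCatch({
    dfs <- list(
      yield = city_series(read_variable_csv(cfg$yield_csv, "yield"), city,
                          "yield", cfg$yield_csv),
      sst = city_series(read_variable_csv(cfg$sst_csv, "sst"), city,
                        "sst", cfg$sst_csv),
      sss = city_series(read_variable_csv(cfg$sss_csv, "sss"), city,
                        "sss", cfg$sss_csv))
    years <- Reduce(intersect, lapply(dfs, function(d) d$year))
    if (length(years) < 8L)
      stop("only ", length(years), " overlapping years for city '", city,
           "'; need at least 8")
    years <- sort(years)
    series <- lapply(names(dfs), function(v) {
      d <- dfs[[v]]
      annual_series(d$value[match(years, d$year)], years,
                    label = paste(city, v),
                    units = c(yield = "tonnes", sst = "degC",
                              sss = "permille")[[v]])
    })
    names(series) <- names(dfs)

    stage <- "detrend"
    base_year <- cfg$base_year %||% max(years)
    dt <- list(yield = hp_filter(series$yield, cfg$lambda))
    rebased <- list(yield = rebase_yield(series$yield, dt$yield, base_year))
    for (v in c("sst", "sss")) {
      if (cfg$detrend_env) {
        dt[[v]] <- hp_filter(series[[v]], cfg$lambda_env)
        # additive rebase: anchor fluctuations at the base-year trend level
        i <- match(base_year, years)
        rebased[[v]] <- annual_series(
          dt[[v]]$trend[i] + dt[[v]]$fluctuation, years,
          label = paste(city, v, "(rebased)"), units = series[[v]]$units)
      } else {
        rebased[[v]] <- series[[v]]
      }
    }

    stage <- "stationarity"
    adf <- lapply(dt, adf_test)
    shp <- lapply(rebased, shape_stats)

    stage <- "marginals"
    scalings <- list()
    marg <- lapply(names(rebased), function(v) {
      x <- rebased[[v]]
      if (cfg$normalize) {
        x <- normalize_series(x)
        scalings[[v]] <<- attr(x, "scaling")
      } else {
        scalings[[v]] <<- list(method = "none", center = 0, scale = 1)
      }
      kde_model(x$values, kernel = cfg$kernel)
    })
    names(marg) <- names(rebased)

    stage <- "copulas"
    ybar <- mean(rebased$yield$values)
    pair_results <- lapply(cfg$pairs, function(v) {
      pobs <- if (cfg$pobs_method == "kde")
        pseudo_obs_from_kde(marg$yield$samples, marg[[v]]$samples,
                            marg$yield, marg[[v]])
      else
        pseudo_obs_ranks(rebased$yield$values, rebased[[v]]$values)
      all_fits <- fit_all_families(pobs)

      rc <- rating_config(expected_yield = ybar, n_sim = cfg$n_sim,
                          coverage_grid = cfg$coverage_grid,
                          seed = city_seed(cfg$seed, paste0(city, ":", v)),
                          denominator = cfg$denominator)
      sims <- simulate_yields(all_fits$best, marg$yield, marg[[v]], rc)
      yields <- denormalize(sims$yield, scalings$yield)
      schedule <- schedule_from_sample(yields, rc,
                                       family = all_fits$best$spec$family)
      list(pobs = pobs, fits = all_fits$fits, best = all_fits$best,
           schedule = schedule)
    })
    names(pair_results) <- cfg$pairs

    structure(list(city = city, years = years, detrend = dt,
                   rebased = rebased, adf = adf, shape = shp,
                   marginals = marg, scalings = scalings,
                   expected_yield = ybar, pairs = pair_results),
              class = "city_result")
  }, error = function(e) {
    stop("city '", city, "', stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(cfg$outdir)) write_city_outputs(result, cfg$outdir)
  result
}

#' @export
print.city_result <- function(x, ...) {
  cat(sprintf("<city_result> %s, years %d-%d, ybar = %.4g\n", x$city,
              min(x$years), max(x$years), x$expected_yield))
  for (v in names(x$pairs)) {
    b <- x$pairs[[v]]$best
    cat(sprintf("  yield-%s: %s theta = %.3f (tau %.3f, D2 %.4f)\n",
                toupper(v), b$spec$family, b$spec$theta, b$kendall_tau,
                b$sq_euclid_dist))
  }
  invisible(x)
}

copula_table <- function(res) {
  do.call(rbind, lapply(names(res$pairs), function(v) {
    do.call(rbind, lapply(res$pairs[[v]]$fits, function(f) {
      data.frame(city = res$city, pair = paste0("yield-", v),
                 family = f$spec$family, theta = f$spec$theta,
                 kendall_tau = f$kendall_tau, sample_tau = f$sample_tau,
                 loglik = f$loglik, sq_euclid_dist = f$sq_euclid_dist,
                 selected = identical(f, res$pairs[[v]]$best))
    }))
  }))
}

rate_table <- function(res) {
  do.call(rbind, lapply(names(res$pairs), function(v) {
    s <- res$pairs[[v]]$schedule
    data.frame(city = res$city, pair = paste0("yield-", v),
               alpha_pct = 100 * s$alpha, rate_pct = 100 * s$rate,
               mc_stderr_pct = 100 * s$mc_stderr)
  }))
}

write_city_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  d <- res$detrend$yield
  utils::write.csv(
    data.frame(year = d$years, actual = d$values, trend = d$trend,
               fluctuation = d$fluctuation,
               rebased = res$rebased$yield$values),
    file.path(outdir, paste0(res$city, "_detrend.csv")), row.names = FALSE)
  utils::write.csv(copula_table(res),
                   file.path(outdir, paste0(res$city, "_copulas.csv")),
                   row.names = FALSE)
  rt <- rate_table(res)
  utils::write.csv(rt, file.path(outdir, paste0(res$city, "_rates_raw.csv")),
                   row.names = FALSE)
  rt$rate_pct <- round(rt$rate_pct, 2)
  rt$mc_stderr_pct <- round(rt$mc_stderr_pct, 3)
  utils::write.csv(rt, file.path(outdir, paste0(res$city, "_rates.csv")),
                   row.names = FALSE)
  invisible(NULL)
}

#' Run the analysis for every city in the inputs
#'
#' Applies [run_city()] to each city, concatenates the fitted-copula and
#' rate tables, and summarises the per-step rate increments across cities
#' (the spread of how fast rates grow with the coverage level).
#'
#' @param cfg A [run_config()].
#' @param cities Cities to analyse; default every city in the yield input.
#' @param keep_going Continue past per-city failures, recording them in
#'   `errors` (default FALSE).
#' @return Object of class `batch_result`: list with `results` (per-city),
#'   `copulas` and `rates` data frames, `span` (per-step rate-increment
#'   summary across cities), and `errors`.
#' @export
run_all <- function(cfg, cities = NULL, keep_going = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cities))
    cities <- unique(read_variable_csv(cfg$yield_csv, "yield")$city)
  results <- list(); errors <- character()
  for (city in cities) {
    r <- tryCatch(run_city(cfg, city), error = function(e) e)
    if (inherits(r, "error")) {
      if (!keep_going) stop(r)
      errors[city] <- conditionMessage(r)
    } else {
      results[[city]] <- r
    }
  }
  copulas <- if (length(results)) do.call(rbind, lapply(results, copula_table))
             else empty_copula_table()
  rates <- if (length(results)) do.call(rbind, lapply(results, rate_table))
           else empty_rate_table()
  rownames(copulas) <- rownames(rates) <- NULL
  span <- rate_span_summary(rates)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(copulas, file.path(cfg$outdir, "copulas_all.csv"),
                     row.names = FALSE)
    utils::write.csv(rates, file.path(cfg$outdir, "rates_all.csv"),
                     row.names = FALSE)
    utils::write.csv(span, file.path(cfg$outdir, "rate_span.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, copulas = copulas, rates = rates,
                 span = span, errors = errors),
            class = "batch_result")
}

empty_copula_table <- function() {
  data.frame(city = character(), pair = character(), family = character(),
             theta = numeric(), kendall_tau = numeric(),
             sample_tau = numeric(), loglik = numeric(),
             sq_euclid_dist = numeric(), selected = logical())
}

empty_rate_table <- function() {
  data.frame(city = character(), pair = character(), alpha_pct = numeric(),
             rate_pct = numeric(), mc_stderr_pct = numeric())
}

#' Rate-increment span across cities
#'
#' For each step of the coverage grid, the increment of the pure rate per
#' city/pair, summarised by its maximum and minimum across cities: the
#' "span" of how strongly rates respond to raising the coverage level.
#'
#' @param rates The concatenated rate table of [run_all()].
#' @return Data frame with columns `from_pct`, `to_pct`, `max_increment_pct`,
#'   `min_increment_pct`.
#' @export
rate_span_summary <- function(rates) {
  if (nrow(rates) == 0L)
    return(data.frame(from_pct = numeric(), to_pct = numeric(),
                      max_increment_pct = numeric(),
                      min_increment_pct = numeric()))
  alphas <- sort(unique(rates$alpha_pct))
  if (length(alphas) < 2L)
    return(data.frame(from_pct = numeric(), to_pct = numeric(),
                      max_increment_pct = numeric(),
                      min_increment_pct = numeric()))
  key <- interaction(rates$city, rates$pair, drop = TRUE)
  steps <- lapply(seq_len(length(alphas) - 1L), function(i) {
    lo <- rates[rates$alpha_pct == alphas[i], ]
    hi <- rates[rates$alpha_pct == alphas[i + 1L], ]
    m <- merge(lo, hi, by = c("city", "pair"), suffixes = c("_lo", "_hi"))
    inc <- m$rate_pct_hi - m$rate_pct_lo
    data.frame(from_pct = alphas[i], to_pct = alphas[i + 1L],
               max_increment_pct = max(inc), min_increment_pct = min(inc))
  })
  do.call(rbind, steps)
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d cities analysed, %d failed\n",
              length(x$results), length(x$errors)))
  if (nrow(x$span)) {
    cat("rate-increment span per coverage step (%):\n")
    print(x$span, row.names = FALSE)
  }
  invisible(x)
}
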