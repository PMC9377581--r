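#' Annual series container
#'
#' Light container for an annual time series of yield (tonnes) or of an
#' environmental extreme (degrees C for SST minima, per-mille for SSS maxima).
#' Years must be consecutive; at least five observations are required so that
#' the downstream trend filter and kernel density estimates are identifiable.
#'
#' @param values Numeric vector of observations, all finite.
#' @param years Integer vector of consecutive calendar years, one per value.
#' @param label Character label carried through to printed output
#'   (e.g. `"Ningbo yield"`).
#' @param units Optional units string (`"tonnes"`, `"degC"`, `"permille"`, or
#'   `""` for dimensionless data).
#'
#' @return An object of class `annual_series`: a list with elements `label`,
#'   `years`, `values`, `units`.
#' @examples
#' annual_series(c(12, 14, 13, 16, 18), 2001:2005, label = "toy yield")
#' @export
annual_series <- function(values, years = seq_along(values), label = "",
                          units = "") {
  values <- as.numeric(values)
  years <- as.integer(years)
  if (length(values) < 5L)
    stop("annual series must have length >= 5, got ", length(values))
  if (length(years) != length(values))
    stop("`years` and `values` lengths differ")
  if (any(!is.finite(values)))
    stop("annual series values must all be finite")
  if (any(diff(years) != 1L))
    stop("`years` must be strictly increasing with step 1")
  structure(list(label = label, years = years, values = values, units = units),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %s%s: %d years (%d-%d)\n",
              x$label, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$values), min(x$years), max(x$years)))
  print(stats::setNames(x$values, x$years))
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$values)

as_annual_series <- function(x, ...) {
  if (inherits(x, "annual_series")) return(x)
  if (is.numeric(x)) return(annual_series(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to annual_series")
}

#' Convert an annual series to a data frame
#'
#' @param x An `annual_series`.
#' @param ... Unused.
#' @return A data frame with columns `year` and `value`.
#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}
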