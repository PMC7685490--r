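#' Daily flow series for a single stream reach
#'
#' The substrate for all hydrologic metrics: a gap-free, strictly increasing
#' daily record of nonnegative discharge for one reach.
#'
#' @param reach_id scalar reach identifier.
#' @param dates `Date` vector, strictly increasing, no gaps.
#' @param discharge numeric vector of nonnegative discharge (m^3/s), aligned
#'   to `dates`.
#' @return a `flow_series` object: a data frame with columns `reach_id`,
#'   `date`, `discharge`.
#' @export
flow_series <- function(reach_id, dates, discharge) {
  stopifnot(length(reach_id) == 1L, inherits(dates, "Date"),
            length(dates) == length(discharge))
  if (length(dates) == 0L) stop("empty flow series")
  dd <- as.integer(diff(dates))
  if (length(dd) && any(dd != 1L))
    stop("dates must be strictly increasing daily values with no gaps")
  if (anyNA(discharge) || any(discharge < 0))
    stop("discharge must be nonnegative and non-missing")
  out <- data.frame(reach_id = reach_id, date = dates, discharge = discharge)
  class(out) <- c("flow_series", "data.frame")
  out
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("<flow_series> reach %s: %d days, %s to %s\n",
              x$reach_id[1], nrow(x), min(x$date), max(x$date)))
  cat(sprintf("  discharge: mean %.4g, max %.4g, zero-flow days %d\n",
              mean(x$discharge), max(x$discharge), sum(x$discharge == 0)))
  invisible(x)
}

as_flow_series <- function(x) {
  if (inherits(x, "flow_series")) return(x)
  flow_series(x$reach_id[1], as.Date(x$date), x$discharge)
}

#' Extract a temporally explicit window from a flow series
#'
#' Returns the sub-series covering whole water years ending with the water
#' year that contains `end_date`. A `horizon` of `"3y"`, `"5y"` or `"10y"`
#' selects that many water years; `"all"` returns the full series.
#'
#' @param series a [flow_series()].
#' @param end_date observation date (a `Date` or coercible string).
#' @param horizon one of `"3y"`, `"5y"`, `"10y"`, `"all"`.
#' @return a `flow_series` spanning exactly the requested water years.
#' @export
extract_window <- function(series, end_date, horizon = c("3y", "5y", "10y", "all")) {
  series <- as_flow_series(series)
  horizon <- match.arg(horizon)
  if (horizon == "all") return(series)
  end_date <- as.Date(end_date)
  n_years <- c("3y" = 3L, "5y" = 5L, "10y" = 10L)[[horizon]]
  wy_end <- water_year(end_date)
  start <- water_year_start(wy_end - n_years + 1L)
  stop_ <- water_year_end(wy_end)
  d0 <- series$date[1]
  dn <- series$date[nrow(series)]
  if (d0 > start || dn < stop_)
    stop(sprintf(
      "series for reach %s does not cover the %s window %s..%s (available from %s to %s)",
      series$reach_id[1], horizon, start, stop_, d0, dn))
  # the series is gap-free daily, so the window is an index range
  idx <- (as.integer(start - d0) + 1L):(as.integer(stop_ - d0) + 1L)
  structure(list(reach_id = rep(series$reach_id[1], length(idx)),
                 date = series$date[idx],
                 discharge = series$discharge[idx]),
            class = c("flow_series", "data.frame"),
            row.names = seq_along(idx))
}
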