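#' Hydrologic metrics from daily streamflow
#'
#' Scalar indices of the daily hydrograph used as habitat-suitability
#' predictors. Each takes the discharge vector of a windowed
#' [flow_series()] and returns one number (or `NA` where the quantity is
#' undefined on that window).
#'
#' `flashiness_rbi()` is the Richards-Baker flashiness index,
#' `sum(|Q[t] - Q[t-1]|) / sum(Q[t])`: the pathlength of day-to-day flow
#' change per unit of total flow. Dimensionless, nonnegative, invariant to
#' uniform rescaling of discharge.
#'
#' @param q numeric vector of daily discharge (a window of one reach's
#'   record), or a `flow_series` whose `discharge` column is used.
#' @return a single numeric value.
#' @examples
#' flashiness_rbi(c(0, 4, 0, 4))   # 1.5
#' @export
flashiness_rbi <- function(q) {
  q <- flow_values(q)
  if (length(q) < 2L) stop("flashiness requires at least 2 days")
  tot <- sum(q)
  if (tot == 0) {
    warning("all-zero flow window: RBI undefined, returning NA")
    return(NA_real_)
  }
  sum(abs(diff(q))) / tot
}

flow_values <- function(q) {
  if (inherits(q, "data.frame")) q <- q$discharge
  if (length(q) == 0L) stop("empty flow window")
  as.numeric(q)
}

#' @rdname flashiness_rbi
#' @param flow_threshold discharge above which a day counts as flowing;
#'   default 0 (any positive flow).
#' @details `hydroperiod()` is the fraction of days with discharge strictly
#'   above `flow_threshold`, in \[0, 1\]; nonincreasing in the threshold.
#' @export
hydroperiod <- function(q, flow_threshold = 0) {
  q <- flow_values(q)
  stopifnot(flow_threshold >= 0)
  mean(q > flow_threshold)
}

#' @rdname flashiness_rbi
#' @details `recession_rate()` is the median daily log-decrement over
#'   recession days, `median(log(Q[t-1]) - log(Q[t]))` taken over days with
#'   strictly decreasing positive flow (`Q[t-1] > Q[t] > 0`). For a pure
#'   geometric recession with daily ratio `r` it equals `-log(r)` exactly.
#'   `NA` when the window contains no recession day.
#' @export
recession_rate <- function(q) {
  q <- flow_values(q)
  if (length(q) < 2L) return(NA_real_)
  prev <- q[-length(q)]
  cur <- q[-1L]
  rec <- prev > cur & cur > 0
  if (!any(rec)) return(NA_real_)
  stats::median(log(prev[rec]) - log(cur[rec]))
}

# Maximal runs of `cond` (logical vector), with runs separated by a gap
# shorter than `min_gap` days merged into one event. Returns a data frame
# with one row per event (start, end indices).
event_runs <- function(cond, min_gap = 2L) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]; e <- ends[r$values]
  if (length(s) <= 1L) return(data.frame(start = s, end = e))
  gaps <- s[-1L] - e[-length(e)] - 1L
  grp <- cumsum(c(TRUE, gaps >= min_gap))
  last_of_grp <- c(diff(grp) > 0L, TRUE)
  data.frame(start = s[!duplicated(grp)], end = e[last_of_grp])
}

#' Storm and drought event metrics
#'
#' Counts maximal runs of days above a storm threshold (storm events) and
#' runs of days at or below a drought threshold (no-flow spells), plus the
#' recency of the last storm. Runs above the storm threshold separated by a
#' single sub-threshold day are merged into one event; a run counts once
#' regardless of length.
#'
#' @inheritParams flashiness_rbi
#' @param storm_threshold discharge above which a day is a storm day. The
#'   default, `NULL`, resolves to 9 times the window median daily flow, a
#'   common effective-discharge convention.
#' @param drought_threshold discharge at or below which a day is a no-flow
#'   day; default 0.
#' @return a list with `storm_count`, `days_since_storm` (days from the last
#'   day of the most recent storm event to the window end; `NA` if no
#'   storm), `drought_count`, and `drought_dur_max` (length in days of the
#'   longest no-flow spell; 0 if none).
#' @examples
#' event_metrics(c(1, 1, 50, 40, 1, 1, 60, 1), storm_threshold = 10)$storm_count  # 2
#' @export
event_metrics <- function(q, storm_threshold = NULL, drought_threshold = 0) {
  q <- flow_values(q)
  if (is.null(storm_threshold)) storm_threshold <- 9 * stats::median(q)
  storms <- event_runs(q > storm_threshold, min_gap = 2L)
  droughts <- event_runs(q <= drought_threshold, min_gap = 1L)
  list(
    storm_count = nrow(storms),
    days_since_storm = if (nrow(storms)) length(q) - max(storms$end) else NA_real_,
    drought_count = nrow(droughts),
    drought_dur_max = if (nrow(droughts)) max(droughts$end - droughts$start + 1L) else 0
  )
}

#' Flow magnitude metrics
#'
#' Percentiles of daily flow (10th, 50th, 90th, linear interpolation between
#' order statistics) and mean seasonal flows (wet season November-April, dry
#' season May-October).
#'
#' @param series a windowed [flow_series()] (dates are needed for the
#'   seasonal means).
#' @return named list: `q10`, `q50`, `q90`, `wet_season_mean`,
#'   `dry_season_mean`.
#' @export
magnitude_metrics <- function(series) {
  series <- as_flow_series(series)
  q <- series$discharge
  qs <- stats::quantile(q, c(0.10, 0.50, 0.90), names = FALSE, type = 7)
  wet <- is_wet_season(series$date)
  list(q10 = qs[1], q50 = qs[2], q90 = qs[3],
       wet_season_mean = if (any(wet)) mean(q[wet]) else NA_real_,
       dry_season_mean = if (any(!wet)) mean(q[!wet]) else NA_real_)
}

#' The fixed registry of hydrologic metrics
#'
#' Names the twelve metrics computed on every window: flashiness (RBI),
#' recession rate, hydroperiod, storm event count and recency, drought
#' (no-flow) event count and longest duration, flow percentiles Q10/Q50/Q90
#' and seasonal mean flows.
#'
#' @return character vector of metric names.
#' @export
hydro_metric_registry <- function() {
  c("rbi", "recession_rate", "hydroperiod",
    "storm_count", "days_since_storm", "drought_count", "drought_dur_max",
    "q10", "q50", "q90", "wet_season_mean", "dry_season_mean")
}

compute_metrics_one_window <- function(win, storm_threshold = NULL,
                                       drought_threshold = 0,
                                       flow_threshold = 0) {
  q <- win$discharge
  ev <- event_metrics(q, storm_threshold, drought_threshold)
  mag <- magnitude_metrics(win)
  rbi <- if (sum(q) == 0) NA_real_ else flashiness_rbi(q)
  c(rbi = rbi,
    recession_rate = recession_rate(q),
    hydroperiod = hydroperiod(q, flow_threshold),
    storm_count = ev$storm_count,
    days_since_storm = ev$days_since_storm,
    drought_count = ev$drought_count,
    drought_dur_max = ev$drought_dur_max,
    q10 = mag$q10, q50 = mag$q50, q90 = mag$q90,
    wet_season_mean = mag$wet_season_mean,
    dry_season_mean = mag$dry_season_mean)
}

#' Full metric vector at every horizon
#'
#' Computes every registry metric on the 3-, 5-, 10-year and full-record
#' windows terminating at the water year of `end_date`. Horizons the series
#' cannot cover are reported as `NA`, never zero; if even the 3-year window
#' is infeasible the call errors.
#'
#' @param series a [flow_series()].
#' @param end_date observation date.
#' @param storm_threshold,drought_threshold,flow_threshold passed to the
#'   event and hydroperiod metrics; the storm threshold (default 9 x window
#'   median) is resolved per window.
#' @return a data frame with columns `reach_id`, `end_date`, `horizon`,
#'   `metric`, `value`: one row per registry metric x horizon (length
#'   `12 * 4` regardless of missingness).
#' @export
compute_metric_vector <- function(series, end_date, storm_threshold = NULL,
                                  drought_threshold = 0, flow_threshold = 0) {
  series <- as_flow_series(series)
  end_date <- as.Date(end_date)
  horizons <- c("3y", "5y", "10y", "all")
  reg <- hydro_metric_registry()
  wins <- lapply(horizons, function(h)
    tryCatch(extract_window(series, end_date, h), error = function(e) NULL))
  if (is.null(wins[[1]]))
    stop(sprintf("reach %s: even the 3-year window ending %s is infeasible",
                 series$reach_id[1], end_date))
  vals <- unlist(lapply(wins, function(win) {
    if (is.null(win)) rep(NA_real_, length(reg))
    else suppressWarnings(
      unname(compute_metrics_one_window(win, storm_threshold,
                                        drought_threshold, flow_threshold)[reg]))
  }))
  out <- data.frame(reach_id = series$reach_id[1], end_date = end_date,
                    horizon = rep(horizons, each = length(reg)),
                    metric = rep(reg, times = length(horizons)),
                    value = vals)
  rownames(out) <- NULL
  out
}

#' Metric table over a grid of reaches and years
#'
#' Convenience wrapper computing [compute_metric_vector()] for every reach
#' in `flows` at one observation date per requested year, stacked into one
#' long table.
#'
#' @param flows named list of [flow_series()] objects.
#' @param years integer vector of observation years.
#' @param month,day observation date within each year (default 15 June).
#' @inheritParams compute_metric_vector
#' @return long metric table (`reach_id`, `end_date`, `horizon`, `metric`,
#'   `value`).
#' @export
compute_metric_table <- function(flows, years, month = 6L, day = 15L,
                                 storm_threshold = NULL,
                                 drought_threshold = 0, flow_threshold = 0) {
  rows <- lapply(flows, function(fs) {
    do.call(rbind, lapply(years, function(y)
      compute_metric_vector(fs, as.Date(sprintf("%d-%02d-%02d", y, month, day)),
                            storm_threshold, drought_threshold, flow_threshold)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a long metric table to one wide row per reach
#'
#' Produces the per-reach feature table consumed by [project_field()]:
#' one row per reach, columns named `metric_horizon`. Where a reach has
#' several end dates the metric values are averaged.
#'
#' @param metric_table long table from [compute_metric_table()].
#' @param horizons horizons to keep (default all four).
#' @return data frame with `reach_id` plus one column per metric x horizon.
#' @export
metrics_wide <- function(metric_table, horizons = c("3y", "5y", "10y", "all")) {
  mt <- metric_table[metric_table$horizon %in% horizons, , drop = FALSE]
  mt$feature <- paste(mt$metric, mt$horizon, sep = "_")
  ag <- stats::aggregate(value ~ reach_id + feature, data = mt,
                         FUN = function(v) mean(v, na.rm = TRUE),
                         na.action = stats::na.pass)
  wide <- stats::reshape(ag, idvar = "reach_id", timevar = "feature",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
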