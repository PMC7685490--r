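#' Regionalize hydrologic metrics to all reaches
#'
#' Trains one random-forest regressor per metric mapping watershed
#' attributes (and any precipitation-derived columns supplied) to the
#' gauged metric values, then predicts the metric for every reach in
#' `targets`. A metric constant across the training reaches is copied as
#' that constant with a warning. Out-of-bag R^2 is reported per metric.
#'
#' @param gauged data frame of training reaches: feature columns plus one
#'   column per metric to regionalize.
#' @param targets data frame of all reaches with the same feature columns.
#' @param metrics character vector of metric column names in `gauged`.
#' @param features character vector of predictor column names (present in
#'   both tables).
#' @param n_trees trees per forest (default 500).
#' @param seed integer seed.
#' @return list with `predictions` (data frame: `reach_id` plus one column
#'   per metric) and `oob_r2` (named numeric).
#' @export
regionalize_metrics <- function(gauged, targets, metrics, features,
                                n_trees = 500L, seed = 1L) {
  if (nrow(gauged) < 20L) stop("need >= 20 gauged training reaches")
  stopifnot(all(features %in% names(gauged)), all(features %in% names(targets)))
  preds <- data.frame(reach_id = targets$reach_id)
  oob <- stats::setNames(numeric(length(metrics)), metrics)
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    yv <- gauged[[m]]
    ok <- !is.na(yv)
    if (length(unique(yv[ok])) < 2L) {
      warning("metric '", m, "' constant in training data; copying constant")
      preds[[m]] <- yv[ok][1]
      oob[i] <- NA_real_
      next
    }
    rf <- with_seed(seed + i, randomForest::randomForest(
      x = gauged[ok, features, drop = FALSE], y = yv[ok], ntree = n_trees))
    preds[[m]] <- unname(stats::predict(rf, targets[, features, drop = FALSE]))
    oob[i] <- rf$rsq[n_trees]
  }
  list(predictions = preds, oob_r2 = oob)
}

#' Project a per-reach probability-of-occurrence field
#'
#' Averages the per-reach metric tables across the supplied GCMs first
#' (element-wise mean), then applies the fitted species distribution model
#' once to the ensemble-mean metrics - so GCM order never matters and
#' identical members reduce to a single-member run.
#'
#' @param model a fitted `flow_sdm` or `temp_sdm`.
#' @param metric_tables_by_gcm a list (one element per GCM) of data frames
#'   with a `reach_id` column and the model's feature columns; reach sets
#'   must match.
#' @param species,driver,period,year_type metadata attached to the field.
#' @return a `ProbabilityField` data frame: `species`, `driver`, `period`,
#'   `year_type`, `reach_id`, `probability`.
#' @export
project_field <- function(model, metric_tables_by_gcm, species = NA,
                          driver = c("flow", "temperature"),
                          period = c("baseline", "end_of_century"),
                          year_type = NA) {
  driver <- match.arg(driver); period <- match.arg(period)
  if (!is.list(metric_tables_by_gcm) || inherits(metric_tables_by_gcm, "data.frame"))
    metric_tables_by_gcm <- list(metric_tables_by_gcm)
  if (any(vapply(metric_tables_by_gcm, is.null, logical(1))))
    stop("missing GCM metric table")
  ref <- metric_tables_by_gcm[[1]]
  num_cols <- setdiff(names(ref), "reach_id")
  for (g in metric_tables_by_gcm[-1]) {
    if (!identical(sort(g$reach_id), sort(ref$reach_id)))
      stop("GCM metric tables disagree on reach set")
  }
  aligned <- lapply(metric_tables_by_gcm, function(g)
    as.matrix(g[match(ref$reach_id, g$reach_id), num_cols, drop = FALSE]))
  # mean as first member plus mean of differences: exactly the identity
  # when all members agree, and order invariant
  ens <- aligned[[1]] +
    Reduce(`+`, lapply(aligned, function(a) a - aligned[[1]])) / length(aligned)
  ens_df <- cbind(data.frame(reach_id = ref$reach_id), as.data.frame(ens))
  p <- stats::predict(model, ens_df)
  data.frame(species = species, driver = driver, period = period,
             year_type = year_type, reach_id = ref$reach_id, probability = p)
}

check_matched_reaches <- function(a, b) {
  only_a <- setdiff(a$reach_id, b$reach_id)
  only_b <- setdiff(b$reach_id, a$reach_id)
  if (length(only_a) || length(only_b))
    stop("reach sets differ: ",
         paste(c(only_a, only_b), collapse = ", "))
}

#' Change in probability of occurrence, end-of-century minus baseline
#'
#' Per-reach difference of two probability fields, plus the regional mean
#' and the 5th/95th percentiles of the per-reach changes.
#'
#' @param baseline,future `ProbabilityField` data frames over the same
#'   reach set.
#' @return a `change_summary` list: `per_reach` (data frame `reach_id`,
#'   `change`), `mean`, `p05`, `p95`.
#' @export
change_map <- function(baseline, future) {
  check_matched_reaches(baseline, future)
  fut <- future$probability[match(baseline$reach_id, future$reach_id)]
  change <- fut - baseline$probability
  qs <- stats::quantile(change, c(0.05, 0.95), names = FALSE, type = 7)
  structure(list(
    per_reach = data.frame(reach_id = baseline$reach_id, change = change),
    mean = mean(change), p05 = qs[1], p95 = qs[2]
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("Change in probability of occurrence: %.3g (%.3g, %.3g)\n",
              x$mean, x$p05, x$p95))
  cat("  (regional mean, with 5th and 95th percentiles across reaches)\n")
  invisible(x)
}

#' Elevation-stratified change comparison
#'
#' Splits per-reach changes at the high/low elevation threshold (high =
#' elevation at or above 375 m) and compares the strata with a Welch
#' two-sample t-test (Wilcoxon rank-sum available via `test`).
#'
#' @param change a `change_summary` from [change_map()].
#' @param attrs watershed attribute table with `reach_id` and `elevation`.
#' @param threshold elevation split in metres (default 375; inclusive on
#'   the high side).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return list: `high_mean`, `low_mean`, `n_high`, `n_low`, `p_value`.
#' @export
stratify_elevation <- function(change, attrs, threshold = 375,
                               test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  pr <- change$per_reach
  elev <- attrs$elevation[match(pr$reach_id, attrs$reach_id)]
  if (anyNA(elev)) stop("attrs does not cover every reach in the change map")
  high <- elev >= threshold
  if (!any(high) || all(high)) stop("empty elevation stratum at ", threshold, " m")
  pv <- tryCatch({
    if (test == "welch") stats::t.test(pr$change[high], pr$change[!high])$p.value
    else stats::wilcox.test(pr$change[high], pr$change[!high],
                            exact = FALSE)$p.value
  }, error = function(e) NA_real_)  # e.g. a single-reach stratum
  list(high_mean = mean(pr$change[high]), low_mean = mean(pr$change[!high]),
       n_high = sum(high), n_low = sum(!high), p_value = pv)
}

#' Annual trend in regional probability of occurrence
#'
#' For a per-year stack of probability fields: the regional mean and the
#' 5th/95th percentile envelope across reaches for each year, and a
#' least-squares linear trend of the annual mean against year (slope in
#' probability per year, with R^2).
#'
#' @param fields_by_year data frame with columns `year`, `reach_id`,
#'   `probability` (>= 3 distinct years).
#' @return a `trend_result` list: `annual` (data frame `year`, `mean`,
#'   `p05`, `p95`), `slope`, `r_squared`.
#' @export
annual_trend <- function(fields_by_year) {
  years <- sort(unique(fields_by_year$year))
  if (length(years) < 3L) stop("need >= 3 years for a trend")
  annual <- do.call(rbind, lapply(years, function(yr) {
    p <- fields_by_year$probability[fields_by_year$year == yr]
    qs <- stats::quantile(p, c(0.05, 0.95), names = FALSE, type = 7)
    data.frame(year = yr, mean = mean(p), p05 = qs[1], p95 = qs[2])
  }))
  fit <- stats::lm(mean ~ year, data = annual)
  structure(list(annual = annual,
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Annual trend: slope = %.4g per year, R^2 = %.2f over %d years\n",
              x$slope, x$r_squared, nrow(x$annual)))
  invisible(x)
}

#' Limiting variable between the two modelled drivers
#'
#' Of the streamflow and stream-temperature probability fields for the same
#' species and period, the driver with the lower probability is the one
#' limiting habitat suitability. Reported per reach and regionally (by the
#' lower mean); exact ties are `"neither"`.
#'
#' @param flow_field,temp_field `ProbabilityField` data frames over the
#'   same reach set.
#' @return list: `per_reach` (data frame `reach_id`, `limiting`),
#'   `regional` (`"flow"`, `"temperature"` or `"neither"`),
#'   `flow_mean`, `temp_mean`.
#' @export
limiting_variable <- function(flow_field, temp_field) {
  check_matched_reaches(flow_field, temp_field)
  tp <- temp_field$probability[match(flow_field$reach_id, temp_field$reach_id)]
  fp <- flow_field$probability
  lim <- ifelse(fp < tp, "flow", ifelse(tp < fp, "temperature", "neither"))
  fm <- mean(fp); tm <- mean(tp)
  regional <- if (fm < tm) "flow" else if (tm < fm) "temperature" else "neither"
  list(per_reach = data.frame(reach_id = flow_field$reach_id, limiting = lim),
       regional = regional, flow_mean = fm, temp_mean = tm)
}

#' Compare all-year versus 3-year (temporally explicit) flow models
#'
#' Fits two random forests on the same records, stratified split and seed:
#' one restricted to the all-year flow features, one to the 3-year
#' features. Reports validation accuracy and out-of-bag error for each, so
#' the value of short-window antecedent conditions can be assessed
#' directly. Species lacking 3-year features are skipped with a message.
#'
#' @param table model table from [build_model_table()].
#' @param n_trees,train_frac,seed as in [fit_flow_sdm()].
#' @return list with `all_year` and `three_year` fitted `flow_sdm` objects
#'   and a `report` data frame (model, n_features, validation_accuracy,
#'   oob_error), or `NULL` (with a message) if 3-year features are absent.
#' @export
compare_temporal_models <- function(table, n_trees = 500L, train_frac = 0.75,
                                    seed = 1L) {
  f_all <- flow_feature_names(table, "all")
  f_3y <- flow_feature_names(table, "3y")
  f_3y <- f_3y[colSums(!is.na(table[, f_3y, drop = FALSE])) > 0]
  if (length(f_3y) == 0L) {
    message("no 3-year features available; skipping temporal comparison")
    return(NULL)
  }
  keep <- stats::complete.cases(table[, c(f_all, f_3y), drop = FALSE])
  d <- table[keep, , drop = FALSE]
  m_all <- fit_flow_sdm(d, f_all, n_trees, train_frac, seed)
  m_3y <- fit_flow_sdm(d, f_3y, n_trees, train_frac, seed)
  list(all_year = m_all, three_year = m_3y,
       report = data.frame(
         model = c("all_year", "three_year"),
         n_features = c(length(f_all), length(f_3y)),
         validation_accuracy = c(m_all$validation_accuracy,
                                 m_3y$validation_accuracy),
         oob_error = c(m_all$oob_error, m_3y$oob_error)))
}
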