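#' Fit the regional weekly stream-temperature model
#'
#' One pooled ordinary-least-squares regression per equation (weekly
#' maximum, minimum, mean stream temperature) over the predictors air
#' temperature, watershed elevation, area, riparian cover and baseflow
#' index, across all reaches and weeks.
#'
#' @param weekly data frame with columns `reach_id`, `year`, `week`,
#'   `tair_c`, `tmax_c`, `tmin_c`, `tmean_c` (observed stream temperatures).
#' @param attrs watershed attribute table (see [gen_watersheds()]); must
#'   cover every reach in `weekly`.
#' @return a `temp_model` object: coefficient matrix (equation x predictor),
#'   residual SD and R^2 per equation.
#' @export
fit_temp_model <- function(weekly, attrs) {
  if (length(unique(weekly$reach_id)) < 2L)
    stop("need >= 2 reaches to identify watershed-attribute effects")
  if (nrow(weekly) < 52L) stop("need >= 52 reach-weeks of training data")
  d <- merge(weekly, attrs, by = "reach_id")
  preds <- c("tair_c", "elevation", "area", "riparian_cover", "baseflow_index")
  fits <- lapply(c("tmax_c", "tmin_c", "tmean_c"), function(resp) {
    f <- stats::as.formula(paste(resp, "~", paste(preds, collapse = " + ")))
    fit <- stats::lm(f, data = d)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design: predictor(s) ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
           " are not identifiable")
    fit
  })
  names(fits) <- c("tmax_c", "tmin_c", "tmean_c")
  co <- t(vapply(fits, stats::coef, numeric(length(preds) + 1L)))
  structure(list(
    coefficients = co,
    predictors = preds,
    sigma = vapply(fits, function(f) summary(f)$sigma, numeric(1)),
    r_squared = vapply(fits, function(f) summary(f)$r.squared, numeric(1)),
    n = nrow(d)
  ), class = "temp_model")
}

#' @export
print.temp_model <- function(x, ...) {
  cat("Regional weekly stream-temperature model (OLS, pooled over reaches)\n")
  cat(sprintf("  training reach-weeks: %d\n", x$n))
  cat("  R^2:", paste(sprintf("%s %.3f", rownames(x$coefficients), x$r_squared),
                      collapse = ", "), "\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.temp_model <- function(object, ...) object$coefficients

#' Predict weekly stream temperatures
#'
#' Applies a fitted [fit_temp_model()] to an air-temperature series. The
#' (max, mean, min) triple is forced to the physical ordering
#' max >= mean >= min by clamping mean into \[min, max\] and swapping
#' inverted max/min pairs; the number of clamped rows is attached as the
#' `"n_clamped"` attribute.
#'
#' @param model a `temp_model`.
#' @param air data frame with `reach_id`, `year`, `week`, `tair_c`.
#' @param attrs watershed attribute table covering every reach in `air`.
#' @return data frame `reach_id`, `year`, `week`, `tmax_c`, `tmin_c`,
#'   `tmean_c`.
#' @export
predict_weekly <- function(model, air, attrs) {
  stopifnot(inherits(model, "temp_model"))
  need <- c("reach_id", "year", "week", "tair_c")
  if (!all(need %in% names(air)))
    stop("air table is missing predictor column(s): ",
         paste(setdiff(need, names(air)), collapse = ", "))
  a <- attrs[match(air$reach_id, attrs$reach_id), ]
  if (anyNA(a$elevation)) stop("attrs does not cover every reach in air")
  X <- cbind(1, air$tair_c, a$elevation, a$area, a$riparian_cover,
             a$baseflow_index)
  tmax <- drop(X %*% model$coefficients["tmax_c", ])
  tmin <- drop(X %*% model$coefficients["tmin_c", ])
  tmean <- drop(X %*% model$coefficients["tmean_c", ])
  lo <- pmin(tmax, tmin); hi <- pmax(tmax, tmin)
  clamped <- sum(tmax < tmin | tmean < lo | tmean > hi)
  out <- data.frame(reach_id = air$reach_id, year = air$year, week = air$week,
                    tmax_c = hi, tmin_c = lo, tmean_c = pmin(pmax(tmean, lo), hi))
  attr(out, "n_clamped") <- clamped
  out
}

#' Six annual stream-temperature metrics
#'
#' Per reach-year: maximum of weekly maxima, mean of weekly maxima, minimum
#' of weekly minima, mean of weekly minima, mean of weekly means, and the
#' annual range (max-of-max minus min-of-min). Reach-years with fewer than
#' `min_weeks` weeks are reported as `NA` rows (missing, not dropped).
#'
#' @param weekly weekly stream temperature table (`reach_id`, `year`,
#'   `week`, `tmax_c`, `tmin_c`, `tmean_c`).
#' @param min_weeks completeness threshold (default 40 weeks).
#' @return data frame `reach_id`, `year`, `tmax_max`, `tmax_mean`,
#'   `tmin_min`, `tmin_mean`, `tmean_mean`, `t_range` (degrees C).
#' @export
annual_temp_metrics <- function(weekly, min_weeks = 40L) {
  groups <- split(weekly, list(weekly$reach_id, weekly$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    g <- g[stats::complete.cases(g[, c("tmax_c", "tmin_c", "tmean_c")]), ]
    base <- data.frame(reach_id = g$reach_id[1] %||% NA, year = g$year[1] %||% NA)
    if (nrow(g) < min_weeks)
      return(cbind(base, tmax_max = NA_real_, tmax_mean = NA_real_,
                   tmin_min = NA_real_, tmin_mean = NA_real_,
                   tmean_mean = NA_real_, t_range = NA_real_))
    cbind(base,
          tmax_max = max(g$tmax_c), tmax_mean = mean(g$tmax_c),
          tmin_min = min(g$tmin_c), tmin_mean = mean(g$tmin_c),
          tmean_mean = mean(g$tmean_c),
          t_range = max(g$tmax_c) - min(g$tmin_c))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$reach_id, out$year), ]
}

#' @rdname annual_temp_metrics
#' @return `temp_metric_names()` returns the six metric column names.
#' @export
temp_metric_names <- function() {
  c("tmax_max", "tmax_mean", "tmin_min", "tmin_mean", "tmean_mean", "t_range")
}
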