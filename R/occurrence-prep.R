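#' Deduplicate species occurrence records
#'
#' Collapses records to one per (species, reach, year, month), the grain at
#' which repeated survey effort in the same reach and month would otherwise
#' pseudo-replicate data-rich streams. Within a merge group any `present`
#' record dominates: presence is stronger evidence than a non-detection.
#' Records without a usable month are rejected (with a message giving the
#' count). The operation is idempotent.
#'
#' @param records data frame with columns `species`, `reach_id`, `year`,
#'   `month`, `status` (`"present"`/`"absent"`).
#' @return deduplicated data frame with an added `source_count` column
#'   giving the number of raw records merged into each row.
#' @export
deduplicate_occurrences <- function(records) {
  need <- c("species", "reach_id", "year", "month", "status")
  stopifnot(all(need %in% names(records)))
  bad <- is.na(records$month) | records$month < 1 | records$month > 12
  if (any(bad)) {
    message(sum(bad), " record(s) rejected: missing or invalid month")
    records <- records[!bad, , drop = FALSE]
  }
  key <- interaction(records$species, records$reach_id, records$year,
                     records$month, drop = TRUE)
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    data.frame(species = g$species[1], reach_id = g$reach_id[1],
               year = g$year[1], month = g$month[1],
               status = if (any(g$status == "present")) "present" else "absent",
               source_count = sum(if ("source_count" %in% names(g))
                 g$source_count else rep(1L, nrow(g))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$reach_id, out$year, out$month), ]
}

#' Join occurrence records to their temporally explicit features
#'
#' For each deduplicated record, computes the full hydrologic metric vector
#' on windows ending at the record's date (mid-month) from that reach's
#' flow series, and joins the six annual stream-temperature metrics for the
#' record's reach-year. Records whose reach lacks even 3-year flow coverage
#' are dropped with a message; horizons that do not fit are `NA` (and such
#' feature columns are left for the model stage to handle).
#'
#' @param records deduplicated occurrence table
#'   (see [deduplicate_occurrences()]).
#' @param flows named list of [flow_series()], one per reach. Ignored when
#'   `metric_table` is supplied.
#' @param temp_metrics annual temperature metric table from
#'   [annual_temp_metrics()] (optional; `NULL` to skip temperature
#'   features).
#' @param metric_table optional precomputed long metric table (from
#'   [compute_metric_table()]); features are then joined by reach and
#'   water year rather than recomputed per record. Windows are water-year
#'   aligned, so every observation date within a water year shares the
#'   same features.
#' @return a data frame: `species`, `reach_id`, `year`, `month`, `status`,
#'   one column per flow metric x horizon (named `metric_horizon`), and the
#'   six temperature metric columns when supplied.
#' @export
build_model_table <- function(records, flows = NULL, temp_metrics = NULL,
                              metric_table = NULL) {
  stopifnot(nrow(records) > 0L)
  end_dates <- as.Date(sprintf("%d-%02d-15", records$year, records$month))
  key <- paste(records$reach_id, water_year(end_dates))
  cache <- new.env(parent = emptyenv())
  if (!is.null(metric_table)) {
    mt_key <- paste(metric_table$reach_id,
                    water_year(as.Date(metric_table$end_date)))
    for (k in unique(mt_key)) {
      f <- metric_table[mt_key == k, , drop = FALSE]
      if (!all(is.na(f$value[f$horizon == "3y"]))) assign(k, f, envir = cache)
    }
  }
  feats <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    k <- key[i]
    if (is.null(cache[[k]]) && is.null(metric_table)) {
      fs <- flows[[records$reach_id[i]]]
      v <- if (is.null(fs)) NULL else tryCatch(
        compute_metric_vector(fs, end_dates[i]), error = function(e) NULL)
      assign(k, if (is.null(v)) NA else v, envir = cache)
    }
    feats[[i]] <- if (is.null(cache[[k]])) NA else cache[[k]]
  }
  ok <- !vapply(feats, function(x) identical(x, NA), logical(1))
  if (sum(!ok) > 0L)
    message(sum(!ok),
            " record(s) dropped: no 3-year flow coverage at the observation date")
  if (!any(ok)) stop("zero usable records after coverage filtering")
  records <- records[ok, , drop = FALSE]
  feats <- feats[ok]
  feat_names <- paste(feats[[1]]$metric, feats[[1]]$horizon, sep = "_")
  wide <- as.data.frame(do.call(rbind, lapply(feats, `[[`, "value")))
  names(wide) <- feat_names
  out <- cbind(records[, c("species", "reach_id", "year", "month", "status")],
               wide)
  if (!is.null(temp_metrics)) {
    tm <- temp_metrics[, c("reach_id", "year", temp_metric_names())]
    out <- merge(out, tm, by = c("reach_id", "year"), all.x = TRUE, sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @rdname build_model_table
#' @param table a model table.
#' @param horizons restrict flow feature columns to these horizons (e.g.
#'   `"3y"` or `"all"` for the temporally explicit comparison).
#' @return `flow_feature_names()` returns the flow feature column names
#'   present in `table`, optionally restricted by horizon.
#' @export
flow_feature_names <- function(table, horizons = c("3y", "5y", "10y", "all")) {
  all_feats <- as.vector(outer(hydro_metric_registry(),
                               c("3y", "5y", "10y", "all"), paste, sep = "_"))
  keep <- intersect(all_feats, names(table))
  keep[sub(".*_", "", keep) %in% horizons]
}
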