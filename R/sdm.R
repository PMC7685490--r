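#' Univariate logistic screening of flow metrics
#'
#' Fits a one-predictor logistic regression of presence/absence on each
#' flow metric x horizon feature and retains those with Wald P <= `alpha`.
#' No multiple-testing correction is applied: the screen feeds a random
#' forest, which tolerates redundant predictors. A more permissive cutoff
#' (e.g. `alpha = 0.2`) is appropriate for species with few observations.
#'
#' @param table model table from [build_model_table()].
#' @param alpha retention P-value cutoff (default 0.05).
#' @param features candidate feature columns (default: all flow features).
#' @return a `data.frame` with one row per screened feature: `metric`,
#'   `estimate`, `p_value`, `n_used`, `retained`; features constant or
#'   all-missing are reported with `NA` statistics and not retained.
#' @export
screen_univariate <- function(table, alpha = 0.05,
                              features = flow_feature_names(table)) {
  y <- as.integer(table$status == "present")
  if (length(y) < 20L) stop("need >= 20 records for screening")
  if (min(table(y)) < 5L)
    stop("fewer than 5 records in the minority class; collect more data")
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    ok <- !is.na(x)
    if (sum(ok) < 20L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L)
      return(data.frame(metric = f, estimate = NA_real_, p_value = NA_real_,
                        n_used = sum(ok), retained = FALSE))
    fit <- suppressWarnings(
      stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2L)  # slope aliased (numerically constant predictor)
      return(data.frame(metric = f, estimate = NA_real_, p_value = NA_real_,
                        n_used = sum(ok), retained = FALSE))
    est <- sm[2, "Estimate"]; p <- sm[2, "Pr(>|z|)"]
    data.frame(metric = f, estimate = est, p_value = p, n_used = sum(ok),
               retained = !is.na(p) && p <= alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

# Stratified train/validation split: samples `train_frac` of each class.
stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    train <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- max(1L, round(train_frac * length(idx)))
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

#' Fit the streamflow species distribution model (random forest)
#'
#' Trains a 500-tree random forest of presence/absence on the retained flow
#' metrics, using a stratified 75% training split, and reports the two
#' headline performance statistics: accuracy on the held-out 25% validation
#' data and the out-of-bag (OOB) error on the training data. Probability of
#' occurrence is the fraction of the 500 trees voting "present".
#'
#' @param table model table from [build_model_table()].
#' @param retained character vector of feature columns to use (typically
#'   the retained set from [screen_univariate()]).
#' @param n_trees number of trees (default 500).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed controlling the split and the forest.
#' @return a `flow_sdm` object with the fitted forest, split indices,
#'   `validation_accuracy` (proportion), `oob_error` (proportion) and the
#'   per-feature importance ranking.
#' @export
fit_flow_sdm <- function(table, retained, n_trees = 500L, train_frac = 0.75,
                         seed = 1L) {
  if (length(retained) == 0L) stop("no metrics survived screening")
  missing_cols <- setdiff(retained, names(table))
  if (length(missing_cols))
    stop("feature column(s) absent from table: ",
         paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(table[, retained, drop = FALSE])
  if (sum(!keep))
    message(sum(!keep), " record(s) dropped for missing retained features")
  d <- table[keep, , drop = FALSE]
  y <- factor(d$status, levels = c("absent", "present"))
  train <- stratified_split(y, train_frac, seed)
  x <- d[, retained, drop = FALSE]
  forest <- with_seed(seed + 1L, randomForest::randomForest(
    x = x[train, , drop = FALSE], y = y[train], ntree = n_trees))
  pred_val <- with_seed(seed + 2L,
    stats::predict(forest, x[!train, , drop = FALSE]))
  imp <- randomForest::importance(forest)
  structure(list(
    forest = forest, retained = retained, n_trees = n_trees,
    train_index = which(train),
    validation_accuracy = mean(pred_val == y[!train]),
    oob_error = unname(forest$err.rate[n_trees, "OOB"]),
    importance = imp[order(-imp[, 1]), 1],
    n = nrow(d), seed = seed
  ), class = "flow_sdm")
}

#' @export
print.flow_sdm <- function(x, ...) {
  cat(sprintf("Streamflow SDM: random forest, %d trees, %d features, n = %d\n",
              x$n_trees, length(x$retained), x$n))
  cat(sprintf("  validation accuracy: %.1f%%   OOB error: %.2f%%\n",
              100 * x$validation_accuracy, 100 * x$oob_error))
  cat("  top features:", paste(utils::head(names(x$importance), 5),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Occurrence probability from the flow SDM
#'
#' The fraction of trees voting "present": an exact multiple of
#' `1/n_trees`, so a 250/250 tie is reported as probability 0.5 rather than
#' forcing a class.
#'
#' @param object a `flow_sdm`.
#' @param newdata data frame containing every retained feature column.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.flow_sdm <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$retained, names(newdata))
  if (length(missing_cols))
    stop("missing retained feature(s): ", paste(missing_cols, collapse = ", "))
  votes <- stats::predict(object$forest,
                          newdata[, object$retained, drop = FALSE],
                          type = "vote", norm.votes = FALSE)
  unname(votes[, "present"] / object$n_trees)
}

#' Fit the stream-temperature species distribution model (PCA + logistic)
#'
#' Standardizes the six annual temperature metrics, reduces them to two
#' principal components to remove their strong collinearity, and fits a
#' logistic regression of presence/absence on the two component scores.
#' Probability of occurrence is `exp(log odds) / (1 + exp(log odds))`.
#' By default standardization and the PCA rotation are estimated from the
#' supplied `scaling_table` (e.g. the pooled baseline plus end-of-century
#' metrics), which may differ from the fitting table.
#'
#' @param table model table with a `status` column and the six temperature
#'   metric columns ([temp_metric_names()]).
#' @param metrics metric columns to use (default the six).
#' @param scaling_table table whose means/SDs and covariance define the
#'   standardization and PCA (default: `table` itself).
#' @return a `temp_sdm` object with standardization parameters, loadings,
#'   variance explained by the two components, and the logistic fit
#'   (coefficients, standard errors, P-values).
#' @export
fit_temp_sdm <- function(table, metrics = temp_metric_names(),
                         scaling_table = table) {
  keep <- stats::complete.cases(table[, metrics, drop = FALSE])
  d <- table[keep, , drop = FALSE]
  y <- as.integer(d$status == "present")
  if (length(unique(y)) < 2L) stop("both classes required to fit")
  sc <- scaling_table[stats::complete.cases(
    scaling_table[, metrics, drop = FALSE]), metrics, drop = FALSE]
  mu <- colMeans(sc)
  sd_ <- apply(sc, 2, stats::sd)
  nondeg <- sd_ > 0
  if (sum(nondeg) < 2L) stop("fewer than 2 nondegenerate temperature metrics")
  metrics <- metrics[nondeg]
  mu <- mu[nondeg]; sd_ <- sd_[nondeg]
  z_sc <- scale(as.matrix(sc[, metrics]), center = mu, scale = sd_)
  pca <- stats::prcomp(z_sc, center = FALSE, scale. = FALSE)
  var_explained <- sum(pca$sdev[1:2]^2) / sum(pca$sdev^2)
  z <- scale(as.matrix(d[, metrics]), center = mu, scale = sd_)
  scores <- z %*% pca$rotation[, 1:2]
  fit <- stats::glm(y ~ scores, family = stats::binomial())
  sm <- summary(fit)$coefficients
  rownames(sm) <- c("(Intercept)", "PC1", "PC2")
  structure(list(
    metrics = metrics, center = mu, scale = sd_,
    rotation = pca$rotation[, 1:2, drop = FALSE],
    var_explained = var_explained,
    coefficients = sm[, "Estimate"],
    coef_table = sm,
    n = nrow(d)
  ), class = "temp_sdm")
}

#' @export
print.temp_sdm <- function(x, ...) {
  cat(sprintf("Stream-temperature SDM: PCA (2 components, %.1f%% variance) + logistic, n = %d\n",
              100 * x$var_explained, x$n))
  print(round(x$coef_table, 4))
  invisible(x)
}

#' @export
coef.temp_sdm <- function(object, ...) object$coefficients

#' Occurrence probability from the temperature SDM
#'
#' Standardizes the metrics with the stored parameters, projects onto the
#' two stored components, and applies the logistic transform to the log
#' odds.
#'
#' @param object a `temp_sdm`.
#' @param newdata data frame containing the six temperature metric columns.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.temp_sdm <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$metrics, names(newdata))
  if (length(missing_cols))
    stop("missing temperature metric(s): ", paste(missing_cols, collapse = ", "))
  z <- scale(as.matrix(newdata[, object$metrics, drop = FALSE]),
             center = object$center, scale = object$scale)
  scores <- z %*% object$rotation
  log_odds <- object$coefficients[1] + drop(scores %*% object$coefficients[2:3])
  unname(logistic(log_odds))
}
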