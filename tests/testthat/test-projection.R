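field_of <- function(p, reaches = sprintf("R%03d", seq_along(p)),
                     driver = "flow", period = "baseline") {
  data.frame(species = "sp", driver = driver, period = period,
             year_type = "wet", reach_id = reaches, probability = p)
}

test_that("metric regionalization learns an elevation-driven metric", {
  ws <- gen_watersheds(200, seed = 61)
  feats <- c("elevation", "area", "riparian_cover", "baseflow_index",
             "drainage_density", "soil_permeability")
  gauged <- ws[1:150, ]
  gauged$m_elev <- 0.002 * gauged$elevation + 0.5  # exact function of elevation
  set.seed(62)
  gauged$m_noise <- rnorm(150)
  out <- regionalize_metrics(gauged, ws, c("m_elev", "m_noise"), feats,
                             n_trees = 300, seed = 63)
  expect_gte(out$oob_r2["m_elev"], 0.9)
  expect_lt(out$oob_r2["m_noise"], 0.2)  # pure noise: no out-of-bag skill
  expect_equal(nrow(out$predictions), 200)
  # deterministic under a fixed seed
  out2 <- regionalize_metrics(gauged, ws, "m_elev", feats,
                              n_trees = 300, seed = 63)
  expect_equal(out$predictions$m_elev, out2$predictions$m_elev)
  # constant metric is copied with a warning
  gauged$m_const <- 1.7
  expect_warning(out3 <- regionalize_metrics(gauged, ws, "m_const", feats,
                                             n_trees = 50, seed = 64),
                 "constant")
  expect_equal(unique(out3$predictions$m_const), 1.7)
  expect_error(regionalize_metrics(gauged[1:10, ], ws, "m_elev", feats),
               ">= 20")
})

test_that("GCM averaging happens before the model and is order invariant", {
  tab <- make_planted_table(500, seed = 65)
  scr <- screen_univariate(tab)
  m <- fit_flow_sdm(tab, scr$metric[scr$retained], seed = 66)
  wide <- metrics_wide(study$metric_table)
  g1 <- wide
  g2 <- wide
  g2[, -1] <- g2[, -1] * 1.1
  g3 <- wide
  g3[, -1] <- g3[, -1] * 0.9
  f_perm1 <- project_field(m, list(g1, g2, g3), period = "baseline")
  f_perm2 <- project_field(m, list(g3, g1, g2), period = "baseline")
  expect_equal(f_perm1$probability, f_perm2$probability)
  # identical members reduce to a single-member run
  f_tripled <- project_field(m, list(g1, g1, g1))
  f_single <- project_field(m, list(g1))
  expect_equal(f_tripled$probability, f_single$probability)
  # vote arithmetic: multiples of 1/500
  expect_true(all(abs(f_single$probability * 500 -
                        round(f_single$probability * 500)) < 1e-9))
  expect_error(project_field(m, list(g1, NULL)), "missing GCM")
})

test_that("change maps difference matched fields with percentile summaries", {
  b <- field_of(rep(0.3, 50))
  f <- field_of(rep(0.5, 50), period = "end_of_century")
  ch <- change_map(b, f)
  expect_equal(ch$mean, 0.2)
  expect_equal(ch$p05, 0.2)
  expect_equal(ch$p95, 0.2)
  # saturated fields: "0 (0, 0)"
  ch0 <- change_map(field_of(rep(1, 50)), field_of(rep(1, 50)))
  expect_equal(c(ch0$mean, ch0$p05, ch0$p95), c(0, 0, 0))
  # future = baseline -> all-zero change
  set.seed(67)
  b2 <- field_of(runif(50))
  expect_true(all(change_map(b2, b2)$per_reach$change == 0))
  # per-reach changes bounded and mean within their range
  f2 <- field_of(runif(50))
  ch2 <- change_map(b2, f2)
  expect_true(all(abs(ch2$per_reach$change) <= 1))
  expect_gte(ch2$mean, min(ch2$per_reach$change))
  expect_lte(ch2$mean, max(ch2$per_reach$change))
  expect_error(change_map(b2, field_of(runif(10))), "reach sets differ")
})

test_that("elevation stratification splits at 375 m inclusive", {
  ws <- study$ws
  n <- nrow(ws)
  set.seed(68)
  ch <- change_map(field_of(runif(n), ws$reach_id),
                   field_of(runif(n), ws$reach_id))
  st <- stratify_elevation(ch, ws)
  high <- ws$elevation >= 375
  expect_equal(st$n_high, sum(high))
  expect_equal(st$high_mean, mean(ch$per_reach$change[high]))
  # a reach at exactly 375 m is high
  ws2 <- data.frame(reach_id = c("A", "B"), elevation = c(375, 100))
  ch2 <- change_map(field_of(c(0.2, 0.4), c("A", "B")),
                    field_of(c(0.5, 0.5), c("A", "B")))
  st2 <- stratify_elevation(ch2, ws2)
  expect_equal(st2$n_high, 1)
  expect_equal(st2$high_mean, 0.3)
  ws3 <- data.frame(reach_id = c("A", "B"), elevation = c(500, 600))
  expect_error(stratify_elevation(ch2, ws3), "empty")
})

test_that("stratum comparison p-values are uniform under the null", {
  # balanced strata so the Welch approximation itself is calibrated
  set.seed(69)
  ws <- data.frame(reach_id = sprintf("R%03d", 1:80),
                   elevation = c(runif(40, 50, 374), runif(40, 376, 2400)))
  n <- nrow(ws)
  pvals <- replicate(200, {
    ch <- change_map(field_of(rep(0, n), ws$reach_id),
                     field_of(rnorm(n, 0, 0.1), ws$reach_id))
    stratify_elevation(ch, ws)$p_value
  })
  # calibration: rejection rate at 0.05 within its binomial band
  ci <- qbinom(c(0.025, 0.975), 200, 0.05) / 200
  expect_gte(mean(pvals < 0.05), ci[1])
  expect_lte(mean(pvals < 0.05), ci[2])
})

test_that("annual trends recover constructed slopes exactly", {
  years <- 2000:2019
  # exactly linear annual means: +0.001/yr
  fields <- do.call(rbind, lapply(years, function(y)
    data.frame(year = y, reach_id = sprintf("R%03d", 1:30),
               probability = 0.3 + 0.001 * (y - 2000))))
  tr <- suppressWarnings(annual_trend(fields))
  expect_equal(tr$slope, 0.001, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-10)
  # constant means: zero slope
  const <- fields
  const$probability <- 0.4
  expect_equal(suppressWarnings(annual_trend(const))$slope, 0)
  # envelope brackets the mean
  set.seed(70)
  noisy <- fields
  noisy$probability <- runif(nrow(noisy))
  trn <- annual_trend(noisy)
  expect_true(all(trn$annual$p05 <= trn$annual$mean &
                    trn$annual$mean <= trn$annual$p95))
  expect_error(annual_trend(fields[fields$year < 2002, ]), ">= 3 years")
})

test_that("the limiting variable is the driver with the lower probability", {
  f <- field_of(rep(0.9, 20))
  t_ <- field_of(rep(0.4, 20), driver = "temperature")
  lv <- limiting_variable(f, t_)
  expect_equal(lv$regional, "temperature")
  expect_true(all(lv$per_reach$limiting == "temperature"))
  # equal fields tie to "neither"
  lv2 <- limiting_variable(f, field_of(rep(0.9, 20), driver = "temperature"))
  expect_equal(lv2$regional, "neither")
  # regional call equals the smaller mean on random pairs
  for (s in 1:5) {
    set.seed(71 + s)
    a <- field_of(runif(30))
    b <- field_of(runif(30), driver = "temperature")
    lv3 <- limiting_variable(a, b)
    expect_equal(lv3$regional,
                 if (mean(a$probability) < mean(b$probability)) "flow"
                 else "temperature")
  }
})

test_that("identical features under both horizons give identical reports", {
  tab <- make_planted_table(400, seed = 72)
  # copy the all-year features over the 3-year columns so both models see
  # the same matrix
  for (m in hydro_metric_registry())
    tab[[paste0(m, "_3y")]] <- tab[[paste0(m, "_all")]]
  cmp <- compare_temporal_models(tab, n_trees = 200, seed = 73)
  expect_equal(cmp$report$validation_accuracy[1],
               cmp$report$validation_accuracy[2])
  expect_equal(cmp$report$oob_error[1], cmp$report$oob_error[2])
})

test_that("a 3-year planted response favors the temporally explicit model", {
  wins <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    tab <- make_planted_table(600, seed = 1100 + s)
    cmp <- compare_temporal_models(tab, n_trees = 300, seed = 1200 + s)
    wins <- wins + (cmp$report$oob_error[cmp$report$model == "three_year"] <=
                      cmp$report$oob_error[cmp$report$model == "all_year"])
  }
  expect_gte(wins / n_seeds, 0.8)
})
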