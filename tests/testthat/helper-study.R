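# Shared synthetic study built once per test run: 40 reaches, water years
# 1982-2014 (the baseline extent), metric table at mid-June observation
# dates once 10-year windows become feasible.
study <- local({
  ws <- gen_watersheds(40, seed = 101)
  pr <- gen_precipitation(ws, 1982:2014, seed = 102)
  fl <- gen_streamflow(pr, ws)
  mt <- compute_metric_table(fl, 1992:2014)
  list(ws = ws, flows = fl, metric_table = mt, years = 1992:2014)
})

# Planted logistic response on a driver metric, scaled to the driver's
# spread: 8 log-odds units per SD (a strong effect whose Bayes accuracy is
# about 0.95), centred so prevalence is near 0.5.
planted_response <- function(metric_table, metric, horizon,
                             effect_per_sd = 8) {
  v <- metric_table$value[metric_table$metric == metric &
                            metric_table$horizon == horizon]
  v <- v[!is.na(v)]
  slope <- effect_per_sd / sd(v)
  list(slope = slope, intercept = -slope * mean(v))
}

# Occurrences planted on a driver metric, prepped into a model table.
make_planted_table <- function(n = 600, seed = 1, metric = "hydroperiod",
                               horizon = "3y", effect_per_sd = 8) {
  resp <- planted_response(study$metric_table, metric, horizon, effect_per_sd)
  occ <- gen_occurrences(study$metric_table, metric, horizon,
                         resp$intercept, resp$slope, n, seed = seed)
  suppressMessages(build_model_table(
    deduplicate_occurrences(occ[, 1:5]), metric_table = study$metric_table))
}
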