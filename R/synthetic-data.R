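#' Synthetic watershed attribute table
#'
#' Generates reach/watershed attributes for a synthetic Mediterranean-climate
#' stream network: elevation (m, bounded by the regional maximum of 2646 m),
#' watershed area (km^2), riparian cover (%), baseflow index (%), and two
#' extra descriptors used by metric regionalization (drainage density,
#' soil permeability). Elevations are forced to span both sides of the 375 m
#' high/low-elevation threshold so elevation-stratified summaries are always
#' defined.
#'
#' @param n_reaches number of reaches (>= 2).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @return data frame with one row per reach.
#' @export
gen_watersheds <- function(n_reaches, seed = 1L) {
  if (n_reaches < 2L)
    stop("n_reaches must be >= 2: elevation stratification is undefined otherwise")
  with_seed(seed, {
    elevation <- stats::runif(n_reaches, 20, 2400)
    # guarantee at least one reach in each elevation stratum
    elevation[1L] <- stats::runif(1, 50, 350)
    elevation[2L] <- stats::runif(1, 400, 2200)
    data.frame(
      reach_id = sprintf("R%03d", seq_len(n_reaches)),
      elevation = elevation,
      area = stats::rlnorm(n_reaches, meanlog = 3, sdlog = 0.8),
      riparian_cover = stats::runif(n_reaches, 0, 100),
      baseflow_index = stats::runif(n_reaches, 5, 80),
      drainage_density = stats::runif(n_reaches, 0.5, 3),
      soil_permeability = stats::runif(n_reaches, 0.1, 1)
    )
  })
}

#' Interannual wetness multipliers
#'
#' Draws one lognormal multiplier per water year (`sdlog = 0.5`, mean 1),
#' giving the strong wet/dry interannual variation typical of
#' Mediterranean-climate precipitation.
#'
#' @param years integer vector of water-year labels.
#' @param seed integer RNG seed.
#' @return named numeric vector of multipliers, one per year.
#' @export
gen_wetness <- function(years, seed = 1L) {
  with_seed(seed, {
    w <- stats::rlnorm(length(years), meanlog = -0.125, sdlog = 0.5)
    stats::setNames(w, years)
  })
}

#' Synthetic daily precipitation
#'
#' Daily per-reach precipitation with Mediterranean seasonality: storm days
#' arrive with probability 0.25 in the wet season (November-April) and 0.015
#' in the dry season (May-October), with gamma-distributed storm depths.
#' Depths scale linearly with the per-year wetness multiplier and with a
#' deterministic orographic factor increasing with reach elevation, so
#' doubling `wetness` for a year exactly doubles that year's totals under a
#' fixed seed.
#'
#' @param reaches watershed table from [gen_watersheds()].
#' @param years water years to simulate.
#' @param wetness named nonnegative multiplier per year (default
#'   [gen_wetness()] on the same seed).
#' @param seed integer RNG seed.
#' @return data frame `reach_id`, `date`, `precip_mm`.
#' @export
gen_precipitation <- function(reaches, years, wetness = NULL, seed = 1L) {
  if (length(years) == 0L) stop("years must be nonempty")
  if (is.null(wetness)) wetness <- gen_wetness(years, seed)
  wetness <- wetness[as.character(years)]
  if (anyNA(wetness)) stop("wetness must supply a multiplier for every year")
  if (any(wetness < 0)) stop("wetness multipliers must be nonnegative")
  dates <- water_year_dates(min(years), max(years))
  wy <- water_year(dates)
  wet <- is_wet_season(dates)
  p_storm <- ifelse(wet, 0.25, 0.015)
  oro <- 0.8 + reaches$elevation / 2646 * 0.8
  with_seed(seed, {
    out <- lapply(seq_len(nrow(reaches)), function(i) {
      storm <- stats::rbinom(length(dates), 1L, p_storm)
      depth <- stats::rgamma(length(dates), shape = 0.8, scale = 15)
      data.frame(reach_id = reaches$reach_id[i], date = dates,
                 precip_mm = storm * depth * oro[i] *
                   unname(wetness[as.character(wy)]))
    })
    do.call(rbind, out)
  })
}

#' Synthetic streamflow from a linear reservoir
#'
#' Routes daily precipitation through a single linear reservoir per reach:
#' storage gains `P_t * area`, loses a seasonal evapotranspiration drain
#' (floored at empty, which produces summer no-flow spells in dry years),
#' and discharges a fixed fraction `k` per day (`Q_t = k * S_t`). With the
#' drain off the system is linear, and a unit pulse recedes geometrically
#' with daily ratio `1 - k`.
#'
#' @param precip daily precipitation table from [gen_precipitation()].
#' @param attrs watershed table from [gen_watersheds()].
#' @param k daily release fraction, in (0, 1]. The default 0.25 gives the
#'   flashy, fast-receding hydrographs characteristic of small
#'   Mediterranean-climate watersheds.
#' @param et_mm_day evapotranspiration drain in mm/day at its summer peak;
#'   follows a seasonal half-sinusoid (zero mid-winter). Set 0 to disable.
#' @param s0 initial storage (mm.km^2 volume units), default 0.
#' @return list of [flow_series()] objects, one per reach, named by
#'   `reach_id`. Discharge is in m^3/s.
#' @export
gen_streamflow <- function(precip, attrs, k = 0.25, et_mm_day = 2, s0 = 0) {
  if (k <= 0 || k > 1) stop("k must lie in (0, 1]")
  # mm.km^2 -> m^3: 1e-3 m * 1e6 m^2; spread over a day -> m^3/s
  to_cms <- 1000 / 86400
  reaches <- split(precip, precip$reach_id)
  out <- lapply(names(reaches), function(rid) {
    p <- reaches[[rid]]
    p <- p[order(p$date), ]
    area <- attrs$area[match(rid, attrs$reach_id)]
    doy <- as.POSIXlt(p$date)$yday
    # ET peaks around day 200 (mid-July), zero in winter
    et <- et_mm_day * pmax(0, sin((doy - 110) / 365 * 2 * pi)) * area
    n <- nrow(p)
    q <- numeric(n)
    s <- s0
    for (t in seq_len(n)) {
      s <- max(s + p$precip_mm[t] * area - et[t], 0)
      q[t] <- k * s
      s <- s - q[t]
    }
    flow_series(rid, p$date, q * to_cms)
  })
  stats::setNames(out, names(reaches))
}

#' Synthetic weekly air and stream temperature
#'
#' Weekly air temperature per reach follows a seasonal cosine with an
#' elevation lapse and a linear warming trend of `warming` degrees C per
#' century (centred on 1998). Weekly stream temperature maximum, minimum and
#' mean are exact linear functions of air temperature and the watershed
#' attributes (elevation, area, riparian cover, baseflow index) given by
#' `true_coeffs`, plus Gaussian noise - so the downstream regression has a
#' known ground truth it must recover.
#'
#' @param attrs watershed table from [gen_watersheds()].
#' @param years calendar years to simulate (52 weeks each).
#' @param warming trend in degrees C per 100 years (default 0).
#' @param true_coeffs list with elements `tmax_c`, `tmin_c`, `tmean_c`, each
#'   a length-6 coefficient vector over (intercept, tair_c, elevation, area,
#'   riparian_cover, baseflow_index). Defaults are physically plausible.
#' @param noise_sd Gaussian noise SD (degrees C) added to each stream
#'   temperature equation; 0 gives exact linearity.
#' @param seed integer RNG seed.
#' @return data frame `reach_id`, `year`, `week`, `tair_c`, `tmax_c`,
#'   `tmin_c`, `tmean_c`.
#' @export
gen_temperature <- function(attrs, years, warming = 0,
                            true_coeffs = default_temp_coeffs(),
                            noise_sd = 0, seed = 1L) {
  for (eq in c("tmax_c", "tmin_c", "tmean_c"))
    if (length(true_coeffs[[eq]]) != 6L)
      stop("true_coeffs$", eq, " must have 6 coefficients")
  grid <- expand.grid(week = 1:52, year = years,
                      reach_id = attrs$reach_id, stringsAsFactors = FALSE)
  a <- attrs[match(grid$reach_id, attrs$reach_id), ]
  with_seed(seed, {
    tair <- 17 - 0.005 * a$elevation +
      8 * cos(2 * pi * (grid$week - 30) / 52) +
      warming * (grid$year - 1998) / 100 +
      stats::rnorm(nrow(grid), 0, noise_sd / 2)
    X <- cbind(1, tair, a$elevation, a$area, a$riparian_cover, a$baseflow_index)
    mk <- function(co) drop(X %*% co) + stats::rnorm(nrow(grid), 0, noise_sd)
    data.frame(reach_id = grid$reach_id, year = grid$year, week = grid$week,
               tair_c = tair,
               tmax_c = mk(true_coeffs$tmax_c),
               tmin_c = mk(true_coeffs$tmin_c),
               tmean_c = mk(true_coeffs$tmean_c))
  })
}

#' @rdname gen_temperature
#' @export
default_temp_coeffs <- function() {
  list(tmax_c  = c(4.0, 0.80, -0.0010, 0.004, -0.020, -0.010),
       tmin_c  = c(-1.0, 0.65, -0.0008, 0.002, -0.010, 0.015),
       tmean_c = c(1.5, 0.72, -0.0009, 0.003, -0.015, 0.005))
}

#' Synthetic categorical trait table with planted clusters
#'
#' Builds `n_clusters` distinct trait prototypes (categorical levels chosen
#' so any two prototypes differ on every trait) and assigns species to them
#' round-robin; each species' traits are then independently corrupted to a
#' different random level with probability `flip_prob`. The true cluster
#' labels are returned so recovery can be scored.
#'
#' @param n_species number of species (>= n_clusters).
#' @param n_clusters number of planted clusters (>= 2).
#' @param n_traits number of categorical traits.
#' @param flip_prob per-trait corruption probability in \[0, 1).
#' @param seed integer RNG seed.
#' @return list with `traits` (data frame of factors, species as rownames)
#'   and `labels` (integer vector of true cluster memberships).
#' @export
gen_traits <- function(n_species, n_clusters, n_traits, flip_prob = 0, seed = 1L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_species < n_clusters) stop("n_species must be >= n_clusters")
  if (flip_prob < 0 || flip_prob >= 1) stop("flip_prob must lie in [0, 1)")
  n_levels <- max(3L, n_clusters)
  lev <- paste0("L", seq_len(n_levels))
  proto <- outer(seq_len(n_clusters), seq_len(n_traits),
                 function(c, k) (c + k) %% n_levels + 1L)
  labels <- rep_len(seq_len(n_clusters), n_species)
  with_seed(seed, {
    m <- proto[labels, , drop = FALSE]
    flip <- matrix(stats::runif(n_species * n_traits) < flip_prob,
                   n_species, n_traits)
    shift <- matrix(sample(n_levels - 1L, n_species * n_traits, replace = TRUE),
                    n_species, n_traits)
    m[flip] <- (m[flip] - 1L + shift[flip]) %% n_levels + 1L
    traits <- as.data.frame(lapply(seq_len(n_traits), function(k)
      factor(lev[m[, k]], levels = lev)))
    names(traits) <- sprintf("trait%02d", seq_len(n_traits))
    rownames(traits) <- sprintf("sp%02d", seq_len(n_species))
    list(traits = traits, labels = labels)
  })
}

#' Synthetic occurrence records from a planted logistic response
#'
#' Draws presence/absence records whose probability follows a known logistic
#' response to one hydrologic driver metric:
#' `p = 1 / (1 + exp(-(intercept + slope * metric)))`. Records sample
#' (reach, end-date) combinations where the driver metric is available in
#' `metric_table`, so responses to short-window (e.g. 3-year) antecedent
#' conditions can be planted and later tested for.
#'
#' @param metric_table long metric table as produced by
#'   [compute_metric_vector()] (columns `reach_id`, `end_date`, `horizon`,
#'   `metric`, `value`).
#' @param driver_metric metric name (must be in the table).
#' @param driver_horizon horizon of the driver (`"3y"`, `"5y"`, `"10y"`,
#'   `"all"`).
#' @param intercept,slope logistic response on the log-odds scale.
#' @param n_records number of records to draw from the available
#'   reach/date combinations (without replacement while the pool lasts, so
#'   records are unique at the deduplication grain whenever possible).
#' @param species species label attached to the records.
#' @param seed integer RNG seed.
#' @return data frame `species`, `reach_id`, `year`, `month`, `status`
#'   (`"present"`/`"absent"`), plus the generating probability `true_p`.
#' @export
gen_occurrences <- function(metric_table, driver_metric, driver_horizon = "3y",
                            intercept = 0, slope = 1, n_records = 500L,
                            species = "sp01", seed = 1L) {
  pool <- metric_table[metric_table$metric == driver_metric &
                         metric_table$horizon == driver_horizon &
                         !is.na(metric_table$value), , drop = FALSE]
  if (nrow(pool) == 0L)
    stop(sprintf("driver metric '%s' at horizon '%s' not present in metric_table",
                 driver_metric, driver_horizon))
  with_seed(seed, {
    idx <- sample(nrow(pool), n_records, replace = n_records > nrow(pool))
    p <- logistic(intercept + slope * pool$value[idx])
    pres <- stats::rbinom(n_records, 1L, p)
    d <- as.Date(pool$end_date[idx])
    lt <- as.POSIXlt(d)
    data.frame(species = species, reach_id = pool$reach_id[idx],
               year = lt$year + 1900L, month = lt$mon + 1L,
               status = ifelse(pres == 1L, "present", "absent"),
               true_p = p)
  })
}
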