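test_that("watershed generator is seeded, bounded, and spans the elevation split", {
  a <- gen_watersheds(10, seed = 1)
  b <- gen_watersheds(10, seed = 1)
  expect_identical(a, b)
  big <- gen_watersheds(100, seed = 7)
  expect_true(any(big$elevation < 375) && any(big$elevation >= 375))
  expect_true(all(big$elevation >= 0 & big$elevation <= 2646))
  expect_true(all(big$riparian_cover >= 0 & big$riparian_cover <= 100))
  expect_true(all(big$baseflow_index >= 0 & big$baseflow_index <= 100))
  expect_false(anyDuplicated(big$reach_id) > 0)
  expect_error(gen_watersheds(1), ">= 2")
})

test_that("precipitation is Mediterranean-seasonal and scales linearly with wetness", {
  ws <- gen_watersheds(5, seed = 2)
  years <- 1991:1995
  w1 <- setNames(rep(1, 5), years)
  p1 <- gen_precipitation(ws, years, wetness = w1, seed = 3)
  expect_true(all(p1$precip_mm >= 0))
  # seasonality: < 15% of annual total falls May-October
  m <- as.integer(format(p1$date, "%m"))
  dry_frac <- sum(p1$precip_mm[m >= 5 & m <= 10]) / sum(p1$precip_mm)
  expect_lt(dry_frac, 0.15)
  # doubling one year's wetness exactly doubles that year's total
  w2 <- w1; w2["1993"] <- 2
  p2 <- gen_precipitation(ws, years, wetness = w2, seed = 3)
  wy1 <- water_year(p1$date)
  expect_equal(sum(p2$precip_mm[wy1 == 1993]), 2 * sum(p1$precip_mm[wy1 == 1993]))
  expect_equal(p2$precip_mm[wy1 != 1993], p1$precip_mm[wy1 != 1993])
  # zero wetness silences a year entirely
  w0 <- w1; w0["1994"] <- 0
  p0 <- gen_precipitation(ws, years, wetness = w0, seed = 3)
  expect_equal(sum(p0$precip_mm[wy1 == 1994]), 0)
  expect_error(gen_precipitation(ws, years, wetness = -w1, seed = 3),
               "nonnegative")
  expect_error(gen_precipitation(ws, integer(0)), "nonempty")
})

test_that("linear reservoir conserves mass, stays nonnegative, recedes geometrically", {
  ws <- gen_watersheds(4, seed = 4)
  pr <- gen_precipitation(ws, 1991:1994, seed = 5)
  fl <- gen_streamflow(pr, ws, k = 0.25, et_mm_day = 2)
  for (rid in names(fl)) {
    q <- fl[[rid]]$discharge
    expect_true(all(q >= 0))
    # mass balance in volume units (cms -> mm.km^2/day is * 86400/1000)
    area <- ws$area[ws$reach_id == rid]
    p_tot <- sum(pr$precip_mm[pr$reach_id == rid]) * area
    expect_lte(sum(q) * 86.4, p_tot + 1e-8)
  }
  # zero precipitation, zero storage -> all-zero flow
  pr0 <- pr; pr0$precip_mm <- 0
  fl0 <- gen_streamflow(pr0, ws)
  expect_true(all(vapply(fl0, function(f) all(f$discharge == 0), logical(1))))
  # unit pulse recession: ratio (1 - k) after the peak, no ET
  pr1 <- pr0
  pr1$precip_mm[pr1$reach_id == "R001"][50] <- 10
  f1 <- gen_streamflow(pr1, ws, k = 0.3, et_mm_day = 0)[["R001"]]$discharge
  post <- f1[50:80]
  expect_equal(post[-1] / post[-length(post)], rep(0.7, 30), tolerance = 1e-12)
  # linearity: doubling precipitation doubles discharge when ET is off
  fl_a <- gen_streamflow(pr, ws, et_mm_day = 0)
  pr2 <- pr; pr2$precip_mm <- 2 * pr$precip_mm
  fl_b <- gen_streamflow(pr2, ws, et_mm_day = 0)
  expect_equal(fl_b[["R002"]]$discharge, 2 * fl_a[["R002"]]$discharge)
  expect_error(gen_streamflow(pr, ws, k = 0), "k must")
  expect_error(gen_streamflow(pr, ws, k = 1.5), "k must")
})

test_that("dry years produce summer no-flow spells", {
  ws <- gen_watersheds(4, seed = 6)
  dry <- setNames(rep(0.3, 3), 1991:1993)
  pr <- gen_precipitation(ws, 1991:1993, wetness = dry, seed = 7)
  fl <- gen_streamflow(pr, ws)
  zero_days <- vapply(fl, function(f) sum(f$discharge == 0), numeric(1))
  expect_true(all(zero_days > 0))
})

test_that("temperature generator plants an exact linear stream-air relation", {
  ws <- gen_watersheds(6, seed = 8)
  co <- default_temp_coeffs()
  tw <- gen_temperature(ws, 1991:1993, warming = 0, noise_sd = 0, seed = 9)
  a <- ws[match(tw$reach_id, ws$reach_id), ]
  X <- cbind(1, tw$tair_c, a$elevation, a$area, a$riparian_cover, a$baseflow_index)
  expect_equal(tw$tmean_c, drop(X %*% co$tmean_c))
  # zero warming, zero noise: identical seasonal cycle every year
  y1 <- tw[tw$year == 1991 & tw$reach_id == "R001", "tair_c"]
  y2 <- tw[tw$year == 1992 & tw$reach_id == "R001", "tair_c"]
  expect_equal(y1, y2)
})

test_that("warming trend shifts end-of-century air temperature by the expected amount", {
  ws <- gen_watersheds(6, seed = 10)
  tw <- gen_temperature(ws, c(1982:2014, 2082:2100), warming = 4,
                        noise_sd = 0.3, seed = 11)
  base <- mean(tw$tair_c[tw$year <= 2014])
  fut <- mean(tw$tair_c[tw$year >= 2082])
  # linear trend of 4 degrees/century; period midpoints 1998 and 2091
  expect_equal(fut - base, 4 * (2091 - 1998) / 100, tolerance = 0.08)
})

test_that("trait generator plants recoverable clusters", {
  g <- gen_traits(12, 3, 20, flip_prob = 0, seed = 12)
  d <- gower_matrix(g$traits)
  same <- outer(g$labels, g$labels, "==")
  expect_true(all(d[same] == 0))
  expect_true(all(d[!same] > 0))
  expect_error(gen_traits(12, 1, 20), "n_clusters")
  expect_error(gen_traits(2, 3, 20), "n_species")
})

test_that("occurrence generator draws Bernoulli from the planted logistic", {
  mt <- study$metric_table
  # slope 0, intercept 0 -> prevalence ~ 0.5 (n = 900, 3 binomial SDs)
  occ <- gen_occurrences(mt, "hydroperiod", "3y", intercept = 0, slope = 0,
                         n_records = 900, seed = 13)
  expect_lt(abs(mean(occ$status == "present") - 0.5), 3 * sqrt(0.25 / 900))
  # near-infinite slope: presence iff metric above the threshold
  resp <- planted_response(mt, "hydroperiod", "3y")
  thresh <- -resp$intercept / resp$slope
  occ2 <- gen_occurrences(mt, "hydroperiod", "3y",
                          intercept = -1e6 * thresh, slope = 1e6,
                          n_records = 200, seed = 14)
  pool <- mt[mt$metric == "hydroperiod" & mt$horizon == "3y", ]
  v <- pool$value[match(paste(occ2$reach_id, occ2$year),
                        paste(pool$reach_id, format(pool$end_date, "%Y")))]
  expect_equal(occ2$status == "present", v > thresh)
  # determinism
  occ3 <- gen_occurrences(mt, "hydroperiod", "3y", resp$intercept, resp$slope,
                          n_records = 100, seed = 15)
  occ4 <- gen_occurrences(mt, "hydroperiod", "3y", resp$intercept, resp$slope,
                          n_records = 100, seed = 15)
  expect_identical(occ3, occ4)
  expect_error(gen_occurrences(mt, "nonexistent_metric", "3y"),
               "nonexistent_metric")
})
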