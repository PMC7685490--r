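# Independent brute-force recomputations of every hydrologic metric,
# written as naive day loops so they share no code path with the package.

oracle_rbi <- function(q) {
  num <- 0
  for (t in 2:length(q)) num <- num + abs(q[t] - q[t - 1])
  num / sum(q)
}

oracle_hydroperiod <- function(q, thr = 0) {
  n_above <- 0
  for (t in seq_along(q)) if (q[t] > thr) n_above <- n_above + 1
  n_above / length(q)
}

oracle_recession <- function(q) {
  decs <- c()
  for (t in 2:length(q))
    if (q[t - 1] > q[t] && q[t] > 0) decs <- c(decs, log(q[t - 1]) - log(q[t]))
  if (length(decs) == 0) return(NA_real_)
  median(decs)
}

# storm events: groups of above-threshold day indices; a new event starts
# when consecutive storm days are more than 2 apart (i.e. separated by at
# least two non-storm days)
oracle_storm_events <- function(q, thr) {
  idx <- which(q > thr)
  if (length(idx) == 0) return(list(count = 0, last_end = NA))
  breaks <- which(diff(idx) > 2)
  list(count = length(breaks) + 1, last_end = idx[length(idx)])
}

# drought spells: groups of at-or-below-threshold indices, split by any gap
oracle_drought_events <- function(q, thr = 0) {
  idx <- which(q <= thr)
  if (length(idx) == 0) return(list(count = 0, max_dur = 0))
  grp <- cumsum(c(1, as.integer(diff(idx) > 1)))
  durs <- as.vector(table(grp))
  list(count = max(grp), max_dur = max(durs))
}

# hand-rolled linear-interpolation quantile (type 7)
oracle_quantile <- function(q, p) {
  x <- sort(q)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

oracle_season_means <- function(q, dates) {
  wet_sum <- dry_sum <- 0; wet_n <- dry_n <- 0
  for (t in seq_along(q)) {
    m <- as.integer(format(dates[t], "%m"))
    if (m >= 11 || m <= 4) { wet_sum <- wet_sum + q[t]; wet_n <- wet_n + 1 }
    else { dry_sum <- dry_sum + q[t]; dry_n <- dry_n + 1 }
  }
  c(wet = wet_sum / wet_n, dry = dry_sum / dry_n)
}

# naive pairwise Gower distance with pairwise deletion of missing traits
oracle_gower <- function(traits) {
  n <- nrow(traits)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mism <- comp <- 0
    for (k in seq_len(ncol(traits))) {
      xi <- traits[i, k]; xj <- traits[j, k]
      if (!is.na(xi) && !is.na(xj)) {
        comp <- comp + 1
        if (xi != xj) mism <- mism + 1
      }
    }
    d[i, j] <- if (comp > 0) mism / comp else NA
  }
  d
}

# naive O(n^3) agglomerative clustering with average/complete/single linkage
oracle_agglomerate <- function(d, linkage = "average") {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- c()
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in 1:(length(active) - 1)) for (b in (a + 1):length(active)) {
      pd <- d[active[[a]], active[[b]], drop = FALSE]
      link <- switch(linkage, average = mean(pd), complete = max(pd),
                     single = min(pd))
      if (link < best_d) { best_d <- link; best <- c(a, b) }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# random 2-water-year flow series with zero spells, for oracle equivalence
random_flow_series <- function(seed) {
  set.seed(seed)
  dates <- seq(as.Date("2000-10-01"), as.Date("2002-09-30"), by = "day")
  q <- rexp(length(dates), rate = 2)
  q[runif(length(dates)) < 0.3] <- 0
  flow_series("RX", dates, q)
}
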