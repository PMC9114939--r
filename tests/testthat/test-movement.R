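# Movement: distances, windowed displacements, effort fields, the ML RMS
# estimator, the jackknife, kernel density and scale comparisons.

test_that("haversine distance matches the spherical law of cosines", {
  expect_equal(great_circle_km(15, -61, 15, -61), 0)
  expect_equal(great_circle_km(0, 0, 1, 0), pi / 180 * 6371, tolerance = 1e-6)
  set.seed(51)
  lat1 <- runif(200, -80, 80); lon1 <- runif(200, -174, 174)
  lat2 <- lat1 + runif(200, -5, 5); lon2 <- lon1 + runif(200, -5, 5)
  expect_equal(great_circle_km(lat1, lon1, lat2, lon2),
               slc_km(lat1, lon1, lat2, lon2), tolerance = 1e-6)
})

test_that("planar projection agrees with haversine inside the study box", {
  set.seed(52)
  lat <- runif(300, 12.5, 17.5); lon <- runif(300, -63.5, -58.5)
  lat2 <- runif(300, 12.5, 17.5); lon2 <- runif(300, -63.5, -58.5)
  p1 <- project_planar(lat, lon); p2 <- project_planar(lat2, lon2)
  d_plan <- sqrt(rowSums((p1 - p2)^2))
  d_hav <- great_circle_km(lat, lon, lat2, lon2)
  keep <- d_hav > 1
  expect_lt(max(abs(d_plan[keep] / d_hav[keep] - 1)), 0.005)
})

test_that("windowed displacements behave on stationary and straight tracks", {
  t0 <- as.POSIXct("2019-02-01 06:00:00", tz = "UTC")
  n <- 73  # 6 h of 5-min fixes
  still <- data.frame(timestamp = t0 + (0:(n - 1)) * 300,
                      lat = 15, lon = -61, track_id = "s")
  d <- window_displacement(still, 1)
  expect_true(all(d$displacement_km == 0))
  # due north at constant speed covering 1 degree of latitude in 6 h
  north <- data.frame(timestamp = t0 + (0:(n - 1)) * 300,
                      lat = 15 + (0:(n - 1)) / (n - 1), lon = -61,
                      track_id = "n")
  d6 <- window_displacement(north, 6, speed_guard_kmh = 30)
  expect_equal(nrow(d6), 1L)
  # first-to-last fix spans 71 of the 72 five-minute steps of the window
  expect_equal(d6$displacement_km, pi / 180 * 6371 * 71 / 72, tolerance = 1e-3)
  # straight-line tracks: mean displacement monotone in window length
  means <- vapply(c(1, 3, 6), function(w)
    mean(window_displacement(north, w, speed_guard_kmh = 30)$displacement_km),
    numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("correlated-walk displacement honours the speed bound and MC oracle", {
  set.seed(53)
  reps <- 40
  ours <- numeric(reps)
  for (r in 1:reps) {
    # 13 fixes span a full hour; the window holds fixes 1..12 (11 steps)
    tr <- gen_crw_track(15, -61, hours = 13 / 12, turn_sd = 0.3, track_id = "w")
    ours[r] <- window_displacement(tr, 1)$displacement_km
  }
  expect_true(all(ours <= 7.41))  # 4 knots for 1 h
  # independent Monte-Carlo oracle of the same walk
  oracle <- replicate(400, {
    h <- cumsum(c(runif(1, 0, 2 * pi), rnorm(10, 0, 0.3)))
    # 12 fixes: displacement accumulates over 11 five-minute steps
    step <- 7.408 / 12
    sqrt(sum(step * sin(h))^2 + sum(step * cos(h))^2)
  })
  se <- sd(oracle) / sqrt(reps)
  expect_lt(abs(mean(ours) - mean(oracle)), 3 * se * sqrt(1 + reps / 400))
})

test_that("effort tallies cells per identification day", {
  t0 <- as.POSIXct("2019-02-01 06:00:00", tz = "UTC")
  gps <- rbind(
    data.frame(timestamp = t0 + (0:11) * 300, lat = 15.01, lon = -61.01,
               track_id = "d1"),
    data.frame(timestamp = t0 + 86400 + (0:11) * 300, lat = 15.01,
               lon = -61.01, track_id = "d2"))
  eff <- build_effort(gps, as.Date(c("2019-02-01", "2019-02-02")), 0.05)
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$effort, 2L)  # two days crossing the same cell
  # only days with identification effort count
  eff1 <- build_effort(gps, as.Date("2019-02-01"), 0.05)
  expect_equal(eff1$effort, 1L)
  # random tracks vs brute-force point-in-cell tally
  set.seed(54)
  gps2 <- data.frame(timestamp = t0 + (0:143) * 300,  # 12 h, one survey day
                     lat = runif(144, 14, 15), lon = runif(144, -62, -61),
                     track_id = "r")
  eff2 <- build_effort(gps2, as.Date("2019-02-01"), 0.1)
  key <- unique(paste(floor(gps2$lon / 0.1), floor(gps2$lat / 0.1)))
  expect_equal(nrow(eff2), length(key))
  expect_true(all(eff2$effort == 1L))
})

test_that("rms_ml hits the lower bound for zero displacement", {
  n <- 30
  s <- data.frame(individual_id = rep(sprintf("w%02d", 1:n), each = 2),
                  date = as.Date("2019-01-01") + c(0, 5),
                  lat = rep(15 + (1:n) / 100, each = 2),
                  lon = rep(-61 + (1:n) / 100, each = 2))
  eff <- uniform_effort(c(14.8, 15.5), c(-61.2, -60.5), 0.05)
  est <- rms_ml(s, eff, lag_bins = c(1, 10))
  expect_equal(est$boundary, "lower")
  expect_lte(est$s_km, 0.11)
})

test_that("rms_ml recovers a known sd and matches a brute-force grid search", {
  set.seed(55)
  n <- 500; s_true <- 10
  x1 <- matrix(runif(2 * n, -40, 40), ncol = 2)
  x2 <- x1 + matrix(rnorm(2 * n, 0, s_true), ncol = 2)
  ll1 <- unproject_planar(x1[, 1], x1[, 2]); ll2 <- unproject_planar(x2[, 1], x2[, 2])
  s <- data.frame(individual_id = rep(sprintf("p%03d", 1:n), 2),
                  date = as.Date("2019-01-01") + rep(c(0, 5), each = n),
                  lat = c(ll1[, 1], ll2[, 1]), lon = c(ll1[, 2], ll2[, 2]))
  eff <- uniform_effort(c(14.5 - 0.9, 14.5 + 0.9), c(-61.9, -60.1), 0.1)
  est <- rms_ml(s, eff, lag_bins = c(1, 10), origin = c(14.5, -61))
  expect_lt(abs(est$s_km - s_true), 1)
  # independent two-stage grid search of the full likelihood, 3 sig figs
  pr <- data.frame(x1 = x1[, 1], y1 = x1[, 2], x2 = x2[, 1], y2 = x2[, 2])
  exy <- project_planar(eff$lat, eff$lon, c(14.5, -61))
  s_grid <- grid_search_s(pr, exy, log(eff$effort), n_coarse = 120, n_fine = 200)
  expect_equal(signif(est$s_km, 3), signif(s_grid, 3), tolerance = 0.005)
})

test_that("jackknife reduces to the closed form at two individuals", {
  set.seed(56)
  mk <- function(id, sd_km) {
    x <- matrix(c(0, 0, rnorm(2, 0, sd_km)), ncol = 2, byrow = TRUE)
    ll <- unproject_planar(x[, 1], x[, 2])
    data.frame(individual_id = id, date = as.Date("2019-01-01") + c(0, 5),
               lat = ll[, 1], lon = ll[, 2])
  }
  s <- rbind(mk("a", 5), mk("b", 40))
  eff <- uniform_effort(c(13, 16), c(-62.5, -59.5), 0.25)
  est <- jackknife_se(s, eff, lag_bins = c(1, 10), origin = c(14.5, -61))
  # leave-one-out estimates recomputed directly
  th <- vapply(c("b", "a"), function(drop) {
    rms_ml(s[s$individual_id != drop, ], eff, lag_bins = c(1, 10),
           origin = c(14.5, -61))$rms_km
  }, numeric(1))
  # n = 2: sqrt(((n-1)/n) * sum (theta_i - mean)^2) = |theta_1 - theta_2| / 2
  expect_equal(est$jackknife_se_km, unname(abs(th[1] - th[2])) / 2,
               tolerance = 1e-6)
})

test_that("jackknife se shrinks as individuals accumulate", {
  eff <- uniform_effort(c(11.5, 17.5), c(-64, -58), 0.5)
  se_for <- function(n_ind, seed) {
    s <- sim_diffusion_sightings(n_ind, 40, 8, 8, seed)
    jackknife_se(s, eff, lag_bins = c(1, 40), origin = c(14.5, -61),
                 max_pairs_per_bin = 300)$jackknife_se_km
  }
  expect_lt(se_for(40, 57), se_for(8, 57))
})

test_that("kernel density conserves mass and locates modes", {
  one <- data.frame(lat = 15.2, lon = -61.1)
  kd <- kernel_density(one, resolution_deg = 0.005, bandwidth_km = 2)
  expect_equal(kd$mass, 1, tolerance = 1e-3)
  expect_true(all(kd$z >= 0))
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  expect_equal(kd$lon[peak[1]], -61.1, tolerance = 0.005)
  expect_equal(kd$lat[peak[2]], 15.2, tolerance = 0.005)
  # two-cloud mixture: argmaxes within one bandwidth of the true centers
  set.seed(58)
  n <- 150
  cloud <- function(lat, lon) data.frame(lat = lat + rnorm(n, 0, 0.02),
                                         lon = lon + rnorm(n, 0, 0.02))
  fx <- rbind(cloud(15.3, -61.3), cloud(14.2, -60.8))
  kd2 <- kernel_density(fx, resolution_deg = 0.01, bandwidth_km = 3)
  expect_equal(kd2$mass, nrow(fx), tolerance = nrow(fx) * 1e-3)
  z <- kd2$z
  top <- which(z == max(z), arr.ind = TRUE)
  d_top <- great_circle_km(kd2$lat[top[2]], kd2$lon[top[1]], c(15.3, 14.2),
                           c(-61.3, -60.8))
  expect_lt(min(d_top), 3)
  # clans with disjoint fixes yield spatially disjoint positive density
  grids <- kernel_density_by_clan(fx, rep(c("A", "B"), each = n),
                                  resolution_deg = 0.01, bandwidth_km = 1)
  expect_equal(length(grids), 2L)
  expect_lt(max(grids$B$lat), min(grids$A$lat))  # B cloud sits well south of A
  expect_equal(grids$A$mass, n, tolerance = 1e-3)
})

test_that("same-island fractions reproduce their defining arithmetic", {
  mk <- function(id, islands, clan) {
    data.frame(individual_id = id,
               date = as.Date(c("2019-02-01", "2020-02-01")),
               island = islands, clan_id = clan)
  }
  rows <- list()
  for (i in 1:17) rows[[length(rows) + 1]] <- mk(paste0("a", i), c("Dominica", "Dominica"), "EC1")
  for (i in 1:6) rows[[length(rows) + 1]] <- mk(paste0("b", i), c("Dominica", "StLucia"), "EC1")
  for (i in 1:5) rows[[length(rows) + 1]] <- mk(paste0("c", i), c("Martinique", "Martinique"), "EC2")
  for (i in 1:7) rows[[length(rows) + 1]] <- mk(paste0("d", i), c("Martinique", "StLucia"), "EC2")
  s <- do.call(rbind, rows)
  f <- same_island_fraction(s)
  ec1 <- f[f$clan_id == "EC1", ]
  ec2 <- f[f$clan_id == "EC2", ]
  expect_equal(ec1$fraction, 17 / 23)
  expect_equal(round(100 * ec1$fraction), 74)
  expect_equal(ec2$fraction, 5 / 12)
  expect_equal(round(100 * ec2$fraction, 1), 41.7)
  # single-year individuals leave the denominator empty
  s1 <- s[s$date == as.Date("2019-02-01"), ]
  f1 <- same_island_fraction(s1)
  expect_true(all(is.na(f1$fraction)))
})

test_that("scale comparison flags order-of-magnitude ratios", {
  ec <- data.frame(quantity = c("yearly_displacement", "mean_group_size"),
                   value = c(100, 8))
  cmp <- compare_scales(ec)
  yr <- cmp[cmp$quantity == "yearly_displacement", ]
  expect_equal(yr$ratio, 10)
  expect_true(yr$flagged)
  # identical inputs: ratios 1, nothing flagged
  self <- compare_scales(etp_reference(), etp_reference())
  expect_true(all(abs(self$ratio - 1) < 1e-12))
  expect_false(any(self$flagged))
  # half-scale reference: ratios 0.5 everywhere
  half <- etp_reference()
  half$value <- half$value / 2
  cmp2 <- compare_scales(etp_reference(), half)
  expect_true(all(abs(cmp2$ratio - 0.5) < 1e-12))
})
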