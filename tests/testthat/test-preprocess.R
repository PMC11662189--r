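test_that("accuracy filter is strict at the threshold", {
  f <- make_fixes(sec = c(0, 10, 20), lat = 25, lon = 121,
                  acc = c(50, 51, 100))
  kept <- filter_accuracy(f, 51)
  expect_equal(kept$accuracy, 50)
  expect_equal(filter_accuracy(make_fixes(1:3 * 10, 25, 121, acc = 100))$accuracy,
               numeric(0))
})

test_that("retention matches the accuracy distribution it is drawn from", {
  set.seed(11)
  # lognormal calibrated so that 95% of draws fall below 47.59 m
  acc <- rlnorm(20000, log(15), 0.702)
  f <- make_fixes(sec = seq_along(acc), lat = 25, lon = 121, acc = acc)
  kept <- filter_accuracy(f, 47.59)
  expect_equal(attr(kept, "retention"), 0.95, tolerance = 0.01)
})

test_that("lowering the threshold never increases retained fixes", {
  set.seed(12)
  f <- make_fixes(sec = 1:500, lat = 25, lon = 121,
                  acc = rlnorm(500, log(15), 0.7))
  counts <- vapply(c(100, 76, 51, 47.59, 20, 10, 5),
                   function(th) nrow(filter_accuracy(f, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("10-s binning averages fixes within a cell", {
  lat <- 25.0400 + (0:9) * 1e-5
  g <- bin_10s(sec = 0:9, lat = lat, lon = rep(121.56, 10))
  expect_equal(sum(!is.na(g$lat)), 1)
  expect_equal(g$lat[1], mean(lat))
  expect_equal(g$n_fixes[1], 10L)
  # a single fix passes through unchanged
  g1 <- bin_10s(sec = 25, lat = 25.041, lon = 121.561)
  expect_equal(g1$lat[3], 25.041)
  expect_equal(nrow(g1), 8640)
})

test_that("binning damps the speed spike of a planted 200 m drift outlier", {
  set.seed(13)
  sec <- 0:119
  lat <- rep(25.04, 120); lon <- rep(121.56, 120)
  lat[60] <- 25.04 + m2lat(200)  # one-second 200 m drift
  raw_speed <- mercator_distance(lat[-120], lon[-120], lat[-1], lon[-1]) / 1
  g <- bin_10s(sec, lat, lon)
  occ <- which(!is.na(g$lat))
  binned_speed <- mercator_distance(g$lat[occ[-length(occ)]],
                                    g$lon[occ[-length(occ)]],
                                    g$lat[occ[-1]], g$lon[occ[-1]]) / 10
  expect_lt(max(binned_speed), max(raw_speed) / 10)
})

test_that("motion threshold is strict: exceeds sqrt(10) m over 10 s", {
  base <- make_pause_grid(0:1)
  move4 <- base
  move4$lat[2] <- base$lat[2] + m2lat(4)
  expect_equal(classify_motion(move4)$state[1:2], c("moving", "moving"))
  move3 <- base
  move3$lat[2] <- base$lat[2] + m2lat(3)
  expect_equal(classify_motion(move3)$state[1:2], c("pause", "pause"))
  exact <- base
  exact$lat[2] <- base$lat[2] + m2lat(sqrt(10))
  expect_equal(classify_motion(exact)$state[1:2], c("pause", "pause"))
})

test_that("isolated observed cells are undefined; absent cells missing", {
  g <- bin_10s(sec = 55, lat = 25.04, lon = 121.56)  # one lone fix
  cg <- classify_motion(g)
  expect_equal(cg$state[6], "undefined")
  expect_equal(sum(cg$state == "missing"), 8639)
})

test_that("every grid cell has exactly one state and counts sum to 8640", {
  set.seed(14)
  sec <- sort(sample(0:86399, 3000))
  lat <- 25.04 + cumsum(rnorm(3000, 0, 1e-6))
  cg <- classify_motion(bin_10s(sec, lat, rep(121.56, 3000)))
  tab <- table(factor(cg$state, levels = c("moving", "pause", "undefined",
                                           "missing")))
  expect_equal(sum(tab), 8640)
  expect_true(all(cg$state %in% c("moving", "pause", "undefined", "missing")))
})

test_that("pause bouts merge under the 300 s / 60 m rule", {
  # two 2-min bouts, 30 m and 120 s apart -> one event
  g <- make_pause_grid(c(0:11, 24:35))
  g$lat[25:36] <- g$lat[25:36] + m2lat(30)
  g <- classify_motion(g)
  ev <- aggregate_pauses(g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 240)
  # same spatial separation but 400 s apart -> two events
  g2 <- make_pause_grid(c(0:11, 52:63))
  g2$lat[53:64] <- g2$lat[53:64] + m2lat(30)
  ev2 <- aggregate_pauses(classify_motion(g2))
  expect_equal(nrow(ev2), 2)
  # a single 10-s pause candidate: cell 0 pauses, cells 1-2 are a flight
  g3 <- make_pause_grid(0:2)
  g3$lat[3] <- g3$lat[3] + m2lat(50)
  ev3 <- aggregate_pauses(classify_motion(g3))
  expect_equal(ev3$duration, 10)
})

test_that("Mercator distance matches its closed-form and haversine oracles", {
  expect_equal(mercator_distance(25, 121, 25, 121), 0)
  # 0.001 degrees of longitude at the equator: arc = 2 pi R / 360 * 0.001
  expect_equal(mercator_distance(0, 0, 0, 0.001),
               2 * pi * 6378137 / 360 * 0.001, tolerance = 1e-6)
  # symmetric
  expect_equal(mercator_distance(25.0, 121.5, 25.01, 121.52),
               mercator_distance(25.01, 121.52, 25.0, 121.5))
  skip_if_not_installed("geosphere")
  set.seed(15)
  n <- 1000
  lat1 <- runif(n, 24.9, 25.1); lon1 <- runif(n, 121.4, 121.7)
  lat2 <- lat1 + m2lat(runif(n, -5000, 5000))
  lon2 <- lon1 + m2lon(runif(n, -5000, 5000))
  ours <- mercator_distance(lat1, lon1, lat2, lon2)
  hav <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
  rel <- abs(ours - hav) / pmax(hav, 1)
  expect_lt(max(rel), 0.005)
})

test_that("imputation is the identity on a complete day", {
  set.seed(16)
  sec <- seq(0, 86399, by = 5)
  lat <- 25.04 + cumsum(rnorm(length(sec), 0, 2e-7))
  g <- classify_motion(bin_10s(sec, lat, rep(121.56, length(sec))))
  reals <- impute_trajectory(g, n_sim = 3, seed = 1)
  for (r in reals) {
    expect_identical(r$lat, g$lat)
    expect_false(any(r$imputed))
  }
})

test_that("a gap flanked by pauses at the same spot fills as that pause", {
  g <- make_pause_grid(c(0:5, 36:41))  # 5-min gap between two bouts
  reals <- impute_trajectory(g, n_sim = 4, seed = 2)
  for (r in reals) {
    expect_true(all(!is.na(r$lat[7:36])))
    expect_true(all(abs(r$lat[7:36] - g$lat[1]) < 1e-12))
    expect_true(all(r$state[7:36] == "pause"))
    expect_true(all(r$imputed[7:36]))
  }
})

test_that("imputation never alters observed cells", {
  set.seed(17)
  sec <- sort(sample(0:86399, 900))
  lat <- 25.04 + cumsum(rnorm(900, 0, 5e-7))
  g <- classify_motion(bin_10s(sec, lat, rep(121.56, 900)))
  obs <- !is.na(g$lat)
  reals <- impute_trajectory(g, n_sim = 5, seed = 3)
  for (r in reals) {
    expect_equal(r$lat[obs], g$lat[obs])
    expect_equal(r$lon[obs], g$lon[obs])
    expect_false(any(r$imputed[obs]))
    expect_false(any(is.na(r$lat)))
  }
})

test_that("a day with no observed points is flagged unimputable", {
  g <- bin_10s(numeric(0), numeric(0), numeric(0))
  expect_null(impute_trajectory(classify_motion(g), n_sim = 2, seed = 1))
})

test_that("across-realization feature spread shrinks with less missingness", {
  cfg <- scenario_config(master_seed = 99)
  routine <- make_routine(cfg, 1)
  sch <- simulate_day_schedule(routine, 0.7, seed = 5)
  fx <- apply_observation_model(sch, cfg, seed = 6)
  g_full <- classify_motion(bin_10s(fx$sec, fx$latitude, fx$longitude))
  spread <- function(g) {
    reals <- impute_trajectory(g, n_sim = 10, seed = 7)
    sd(vapply(reals, function(r)
      .subset2(daily_features(r, home_cluster(routine$home_lat,
                                              routine$home_lon)),
               "total_distance"), 0))
  }
  # denser observation: halve the off-window by keeping two on-minutes
  cfg2 <- cfg; cfg2$duty_on_s <- 240; cfg2$duty_off_s <- 420
  fx2 <- apply_observation_model(sch, cfg2, seed = 6)
  g_dense <- classify_motion(bin_10s(fx2$sec, fx2$latitude, fx2$longitude))
  expect_lt(spread(g_dense), spread(g_full))
})

test_that("imputation-averaged distance beats observed-only distance", {
  ib <- experiment_imputation_benefit(n_days = 6, seed = 21)
  expect_lt(ib$mae_imputed, ib$mae_observed)
})
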