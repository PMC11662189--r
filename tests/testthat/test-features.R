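test_that("cluster count reflects spatial structure of pauses", {
  set.seed(31)
  one <- data.frame(lat = 25.04 + m2lat(rnorm(30, 0, 40)),
                    lon = 121.56 + m2lon(rnorm(30, 0, 40)),
                    duration = runif(30, 300, 3600))
  expect_equal(nrow(cluster_locations(one, d_max = 500)), 1)
  two <- rbind(one, within(one, lat <- lat + m2lat(5000)))
  expect_equal(nrow(cluster_locations(two, d_max = 500)), 2)
  expect_warning(empty <- cluster_locations(one[0, ]), "no pause")
  expect_equal(nrow(empty), 0)
})

test_that("three planted sites separated by > 2 d_max are recovered", {
  set.seed(32)
  centers <- list(c(0, 0), c(1500, 0), c(0, 2000))  # meters apart
  pauses <- do.call(rbind, lapply(seq_along(centers), function(k) {
    data.frame(site = k,
               lat = 25.04 + m2lat(centers[[k]][1] + rnorm(25, 0, 30)),
               lon = 121.56 + m2lon(centers[[k]][2] + rnorm(25, 0, 30)),
               duration = runif(25, 600, 7200))
  }))
  cl <- cluster_locations(pauses[, -1], d_max = 500)
  expect_equal(nrow(cl), 3)
  got <- assign_clusters(pauses, cl)
  # planted labels and recovered labels agree up to relabeling
  expect_equal(length(unique(paste(pauses$site, got))), 3)
})

test_that("home is the cluster holding the nocturnal pause time", {
  mk <- function(lat, lon, t0, t1)
    data.frame(lat = lat, lon = lon, t_begin = t0, t_end = t1,
               duration = t1 - t0)
  pauses <- rbind(mk(25.04, 121.56, 0, 6 * 3600),          # night at home
                  mk(25.06, 121.58, 9 * 3600, 18 * 3600))  # long day at work
  cl <- cluster_locations(pauses, d_max = 500)
  cl <- infer_home(cl, pauses)
  expect_equal(sum(cl$is_home), 1)
  expect_equal(cl$lat[cl$is_home], 25.04, tolerance = 1e-6)
  # 80/20 split of night time
  p2 <- rbind(mk(25.04, 121.56, 0, 4.8 * 3600),
              mk(25.06, 121.58, 4.8 * 3600, 6 * 3600))
  c2 <- infer_home(cluster_locations(p2, d_max = 500), p2)
  expect_equal(c2$lat[c2$is_home], 25.04, tolerance = 1e-6)
})

test_that("home is identified for every simulated home/office routine", {
  cfg <- scenario_config(n_participants = 20, master_seed = 77)
  hits <- vapply(1:20, function(i) {
    r <- make_routine(cfg, i)
    # explicit 22:00-08:00 home, 09:00-18:00 office days
    pauses <- do.call(rbind, lapply(1:7, function(d)
      data.frame(lat = c(r$home_lat, r$site_lat[1], r$home_lat),
                 lon = c(r$home_lon, r$site_lon[1], r$home_lon),
                 t_begin = c(0, 9, 22) * 3600,
                 t_end = c(8, 18, 24) * 3600,
                 duration = c(8, 9, 2) * 3600)))
    cl <- infer_home(cluster_locations(pauses, d_max = 500), pauses)
    abs(cl$lat[cl$is_home] - r$home_lat) < m2lat(100)
  }, TRUE)
  expect_equal(sum(hits), 20L)
})

test_that("a fully stationary home day has degenerate features", {
  g <- make_pause_grid(0:8639)
  f <- daily_features(g, home_cluster(), coverage = 1)
  expect_equal(f$homestay, 1)
  expect_equal(f$transition_time, 0)
  expect_equal(f$total_distance, 0)
  expect_equal(f$normalized_entropy, 0)
  expect_equal(f$n_clusters, 1)
})

test_that("entropy closed forms hold to 1e-9", {
  # equal pause time at exactly two clusters -> normalized entropy 1
  cl2 <- data.frame(cluster = 1:2, lat = c(25.04, 25.10),
                    lon = 121.56, total_pause_seconds = 1,
                    is_home = c(TRUE, FALSE))
  # a one-cell gap separates the bouts so no boundary cell turns "moving"
  g <- make_pause_grid(c(0:499, 502:1001))
  g$lat[503:1002] <- 25.10
  g <- classify_motion(g)
  f <- daily_features(g, cl2, coverage = 1)
  expect_equal(f$normalized_entropy, 1, tolerance = 1e-9)
  # (0.75, 0.25) split
  g2 <- make_pause_grid(c(0:749, 752:1001))
  g2$lat[753:1002] <- 25.10
  g2 <- classify_motion(g2)
  f2 <- daily_features(g2, cl2, coverage = 1)
  ent <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(f2$normalized_entropy, ent / log(2), tolerance = 1e-9)
  expect_equal(ent, 0.5623351, tolerance = 1e-6)
  expect_equal(ent / log(2), 0.8112781, tolerance = 1e-6)
  expect_equal(f2$homestay, 0.75, tolerance = 1e-9)
})

test_that("features are invariant to a longitude translation", {
  set.seed(33)
  sec <- sort(sample(0:86399, 4000))
  lat <- 25.04 + m2lat(cumsum(rnorm(4000, 0, 1)))
  lon <- 121.56 + m2lon(cumsum(rnorm(4000, 0, 1)))
  g1 <- classify_motion(bin_10s(sec, lat, lon))
  g2 <- classify_motion(bin_10s(sec, lat, lon + 1))
  cl1 <- home_cluster(25.04, 121.56)
  cl2 <- home_cluster(25.04, 122.56)
  f1 <- daily_features(g1, cl1, coverage = 1)
  f2 <- daily_features(g2, cl2, coverage = 1)
  for (v in c("location_variance", "speed_mean", "total_distance",
              "transition_time", "normalized_entropy", "homestay"))
    expect_equal(f1[[v]], f2[[v]], tolerance = 1e-7, label = v)
})

test_that("homestay and away fractions of pause time sum to one", {
  cl2 <- data.frame(cluster = 1:2, lat = c(25.04, 25.10), lon = 121.56,
                    total_pause_seconds = 1, is_home = c(TRUE, FALSE))
  g <- make_pause_grid(c(0:599, 602:1001))
  g$lat[603:1002] <- 25.10
  g <- classify_motion(g)
  f <- daily_features(g, cl2, coverage = 1)
  # all non-missing time is pause time here, so homestay is the home share
  expect_equal(f$homestay + 0.4, 1)
})

test_that("subsampling a trajectory never increases total distance", {
  cfg <- scenario_config(master_seed = 31)
  r <- make_routine(cfg, 2)
  sch <- simulate_day_schedule(r, 0.6, seed = 9)
  truth <- true_features_from_schedule(sch, cfg$gps_noise_sd)
  cfg0 <- cfg; cfg0$gps_noise_sd <- 0
  fx <- apply_observation_model(sch, cfg0, seed = 10)
  keep <- seq(1, nrow(fx), by = 4)  # additional subsampling
  for (sel in list(seq_len(nrow(fx)), keep)) {
    g <- classify_motion(bin_10s(fx$sec[sel], fx$latitude[sel],
                                 fx$longitude[sel]))
    f <- daily_features(g, home_cluster(r$home_lat, r$home_lon),
                        coverage = mean(!is.na(g$lat)))
    expect_lte(f$total_distance, truth[["total_distance"]] * 1.001)
  }
})

test_that("total distance dominates the first-to-last displacement", {
  set.seed(34)
  sec <- seq(0, 1430, by = 10)  # 2 km traverse at walking pace
  lat <- 25.04 + m2lat(seq(0, 2000, length.out = length(sec)))
  g <- classify_motion(bin_10s(sec, lat, rep(121.56, length(sec))))
  f <- daily_features(g, home_cluster(), coverage = 1)
  occ <- which(!is.na(g$lat))
  straight <- mercator_distance(g$lat[occ[1]], g$lon[occ[1]],
                                g$lat[occ[length(occ)]], g$lon[occ[length(occ)]])
  expect_gte(f$total_distance, straight * 0.999)
})
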