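# In-code fixtures shared across test files.

# A data.frame of GPS fixes with the canonical loaded columns.
make_fixes <- function(sec, lat, lon, acc = 10,
                       day = as.Date("2020-03-16"), offset_hours = 8) {
  t_loc <- as.POSIXct(day, tz = "UTC") + sec
  data.frame(t_utc = t_loc - offset_hours * 3600,
             latitude = lat, longitude = lon,
             altitude = 15, accuracy = rep_len(acc, length(sec)))
}

# Write fixes as a Beiwe-dialect CSV and return the path.
write_fix_csv <- function(fixes, path = tempfile(fileext = ".csv")) {
  write_gps(fixes, path)
  path
}

# A classified day grid holding a stationary bout at (lat0, lon0) over the
# given cells; everything else missing.
make_pause_grid <- function(cells, lat0 = 25.04, lon0 = 121.56) {
  g <- bin_10s(numeric(0), numeric(0), numeric(0))
  g$lat[cells + 1L] <- lat0
  g$lon[cells + 1L] <- lon0
  classify_motion(g)
}

# Meters to degrees around Taipei latitude, matching the generator.
m2lat <- function(m) m / 111320
m2lon <- function(m, lat = 25.04) m / (111320 * cos(lat * pi / 180))

# A one-cluster "home" table for feature computation.
home_cluster <- function(lat = 25.04, lon = 121.56) {
  data.frame(cluster = 1L, lat = lat, lon = lon,
             total_pause_seconds = 3600, is_home = TRUE)
}

# Day-pair fixture with a planted delta-effect, AR(1) within-person noise.
make_pairs <- function(n_part = 40, n_pairs = 170, beta = 0.5,
                       ar = 0.3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_part), function(p) {
    e <- as.numeric(stats::arima.sim(list(ar = ar), n_pairs))
    d_hs <- rnorm(n_pairs, 0, 0.2)
    hs1 <- runif(n_pairs, 0.3, 0.9)
    data.frame(participant = sprintf("P%02d", p),
               day_index = seq_len(n_pairs),
               age = sample(25:60, 1), sex = rbinom(1, 1, 0.4),
               d_homestay = d_hs, homestay_1 = hs1,
               homestay_2 = hs1 + d_hs,
               depressed_2 = beta * d_hs + 0.1 * hs1 + e)
  })
  do.call(rbind, rows)
}
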