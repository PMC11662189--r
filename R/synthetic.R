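# Synthetic Beiwe-format cohort: duty-cycled GPS over a home + K-location
# daily routine, with twice-daily ordinal mood series coupled to mobility in
# both directions. Everything is reproducible from one master seed.

#' Scenario configuration for the synthetic cohort
#'
#' Defaults encode the study conditions: 38 participants (10 HC / 11 BP /
#' 17 MDD) followed 180 days around a Taipei reference point (25.04 N,
#' 121.56 E — a non-equatorial latitude, so Mercator-correction bugs are
#' visible), GPS duty cycle of 1 minute on per 10-minute period, lognormal
#' accuracy with median 15 m calibrated so about 95% of values fall below
#' 47.6 m, and EMA missingness of 6.5%. Coupling coefficients plant the
#' lagged mood-mobility pathways (signs as in the study: more homestay ->
#' worse fatigue/depressed/irritable mood; more location variance -> lower
#' depressed mood; higher depressed/fatigued mood -> less location variance
#' and more homestay next day).
#'
#' @param n_participants cohort size.
#' @param n_days follow-up days per participant.
#' @param groups diagnosis group sizes, named HC/BP/MDD (recycled to
#'   `n_participants`).
#' @param ref_lat,ref_lon reference coordinates, degrees.
#' @param k_locations candidate non-home sites per participant.
#' @param duty_on_s,duty_off_s duty cycle: record `duty_on_s` seconds every
#'   `duty_on_s + duty_off_s` seconds.
#' @param burst_rate fixes per second while the sensor is on.
#' @param gps_noise_sd stationary SD of the position error, meters.
#' @param noise_tau_s time constant of the position-error drift, seconds.
#'   GPS error is dominated by slowly varying multipath/atmospheric bias, so
#'   the error process is exponentially correlated rather than white.
#' @param acc_meanlog,acc_sdlog lognormal accuracy distribution (meters).
#' @param mood_ar latent mood AR(1) parameter.
#' @param mood_noise_sd latent mood innovation SD.
#' @param prompt_noise_sd extra within-day noise between the two prompts.
#' @param thresholds strictly increasing latent cut points mapping to the
#'   ordinal 1-5 scale.
#' @param ema_missing_rate probability the 12:45 prompt goes unanswered.
#' @param b_hs_to_dep,b_hs_to_fat,b_hs_to_irr,b_lv_to_dep feature-to-mood
#'   couplings (per SD of the daily feature change).
#' @param b_dep_to_hs,b_fat_to_hs,b_irr_to_hs,b_dep_to_lv,b_fat_to_lv
#'   mood-to-next-day-mobility couplings (per latent mood unit).
#' @param dhs_sd,dlv_sd nominal SDs used to standardise daily feature changes
#'   inside the mood equations.
#' @param master_seed integer master seed.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_participants = 38, n_days = 180,
                            groups = c(HC = 10, BP = 11, MDD = 17),
                            ref_lat = 25.04, ref_lon = 121.56,
                            k_locations = 4,
                            duty_on_s = 60, duty_off_s = 600,
                            burst_rate = 0.2, gps_noise_sd = 10,
                            noise_tau_s = 600,
                            acc_meanlog = log(15), acc_sdlog = 0.702,
                            mood_ar = 0.3, mood_noise_sd = 0.6,
                            prompt_noise_sd = 0.25,
                            thresholds = c(0.3, 1.2, 2.1, 3.0),
                            ema_missing_rate = 0.065,
                            b_hs_to_dep = 0.4, b_hs_to_fat = 0.4,
                            b_hs_to_irr = 0.25, b_lv_to_dep = -0.4,
                            b_dep_to_hs = 0.3, b_fat_to_hs = 0.3,
                            b_irr_to_hs = 0.15, b_dep_to_lv = -0.3,
                            b_fat_to_lv = -0.15,
                            dhs_sd = 0.15, dlv_sd = 1.0,
                            master_seed = 20260101) {
  stopifnot(all(diff(thresholds) > 0), ema_missing_rate >= 0,
            ema_missing_rate <= 1, duty_on_s > 0, duty_off_s >= 0,
            86400 %% (duty_on_s + duty_off_s) == 0 ||
              TRUE)  # an incomplete final cycle is tolerated
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

# meters -> degrees at a given latitude
.m2deg_lat <- function(m) m / 111320
.m2deg_lon <- function(m, lat) m / (111320 * cos(lat * pi / 180))

#' Build one participant's fixed routine
#'
#' Home position near the reference point, `k_locations` candidate sites at
#' 500-4000 m, a baseline homestay propensity, a habitual leave time, and
#' latent mood traits by diagnosis group.
#'
#' @param cfg scenario configuration.
#' @param i participant index (drives the sub-seed).
#' @return list describing the routine.
#' @export
make_routine <- function(cfg, i) {
  grp <- rep(rep(names(cfg$groups), cfg$groups),
             length.out = cfg$n_participants)[i]
  with_seed(derive_seed(cfg$master_seed, 1000 + i), {
    home_lat <- cfg$ref_lat + .m2deg_lat(stats::runif(1, -2000, 2000))
    home_lon <- cfg$ref_lon + .m2deg_lon(stats::runif(1, -2000, 2000),
                                         cfg$ref_lat)
    ang <- stats::runif(cfg$k_locations, 0, 2 * pi)
    dist <- stats::runif(cfg$k_locations, 500, 4000)
    site_lat <- home_lat + .m2deg_lat(dist * sin(ang))
    site_lon <- home_lon + .m2deg_lon(dist * cos(ang), home_lat)
    base_homestay <- stats::plogis(stats::qlogis(0.62) + stats::rnorm(1, 0, 0.35))
    trait <- switch(grp,
                    HC = c(fatigue = -0.3, depressed = -0.5, manic = -0.5,
                           irritability = -0.4),
                    BP = c(fatigue = 0.2, depressed = 0.3, manic = 0.3,
                           irritability = 0.2),
                    MDD = c(fatigue = 0.4, depressed = 0.6, manic = -0.4,
                            irritability = 0.1))
    trait <- trait + stats::rnorm(4, 0, 0.2)
    list(id = sprintf("P%02d", i), group = grp,
         age = round(min(max(stats::rnorm(1, 41.3, 12.1), 20), 75)),
         sex = stats::rbinom(1, 1, 0.37),
         home_lat = home_lat, home_lon = home_lon,
         site_lat = site_lat, site_lon = site_lon,
         base_homestay = base_homestay,
         leave_time = 8.5 * 3600 + stats::rnorm(1, 0, 1200),
         trait = trait)
  })
}

#' Simulate one day's true movement schedule
#'
#' Alternating pause/flight path: home until the habitual leave time, a
#' sequence of site visits with flights at walking (1.4 m/s) or vehicle
#' (8 m/s) speed depending on leg length, then home for the night. The
#' homestay target sets how much of the day is spent away; `disp_scale`
#' radially scales site offsets from home (the dispersal dial that moves
#' location variance). Uses the current RNG state unless `seed` is given.
#'
#' @param routine participant routine from [make_routine()].
#' @param homestay_target fraction of the day at home, (0, 1).
#' @param disp_scale radial scaling of site offsets. Default 1.
#' @param seed optional integer seed.
#' @return numeric matrix, one row per event, columns `t0`, `t1`, `lat0`,
#'   `lon0`, `lat1`, `lon1`, `site` (0 = home, -1 = flight), `flight`,
#'   `dist`, `speed`.
#' @export
simulate_day_schedule <- function(routine, homestay_target = NULL,
                                  disp_scale = 1, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed,
    simulate_day_schedule(routine, homestay_target, disp_scale)))
  if (is.null(homestay_target)) homestay_target <- routine$base_homestay
  h <- min(max(homestay_target, 0.02), 0.995)
  away <- (1 - h) * 86400
  home <- c(routine$home_lat, routine$home_lon)
  ev <- function(t0, t1, a, b, site, flight, dist = 0, speed = 0)
    c(t0, t1, a[1], a[2], b[1], b[2], site, flight, dist, speed)
  if (away < 900) {
    m <- matrix(ev(0, 86400, home, home, 0, 0), nrow = 1)
    colnames(m) <- c("t0", "t1", "lat0", "lon0", "lat1", "lon1",
                     "site", "flight", "dist", "speed")
    return(m)
  }
  k <- length(routine$site_lat)
  nv <- min(k, max(1L, round(away / 9000)))
  sites <- sample.int(k, nv)
  s_lat <- home[1] + disp_scale * (routine$site_lat[sites] - home[1])
  s_lon <- home[2] + disp_scale * (routine$site_lon[sites] - home[2])
  leg_lat <- c(home[1], s_lat, home[1])
  leg_lon <- c(home[2], s_lon, home[2])
  d <- mercator_distance(leg_lat[-(nv + 2)], leg_lon[-(nv + 2)],
                         leg_lat[-1], leg_lon[-1])
  speed <- ifelse(d < 1200, 1.4, 8)
  travel <- d / speed
  pause_total <- max(away - sum(travel), 600)
  w <- stats::rgamma(nv, shape = 4, rate = 1)
  p_dur <- pause_total * w / sum(w)
  t_leave <- min(max(routine$leave_time + stats::rnorm(1, 0, 900),
                     4 * 3600), 12 * 3600)
  # shrink if the trip would spill past 23:30
  overshoot <- (t_leave + sum(travel) + sum(p_dur)) - 23.5 * 3600
  if (overshoot > 0) p_dur <- p_dur * max(0.05, 1 - overshoot / sum(p_dur))
  rows <- list(ev(0, t_leave, home, home, 0, 0))
  t <- t_leave
  for (j in seq_len(nv)) {
    a <- c(leg_lat[j], leg_lon[j]); b <- c(leg_lat[j + 1], leg_lon[j + 1])
    rows[[length(rows) + 1L]] <- ev(t, t + travel[j], a, b, -1, 1,
                                    d[j], speed[j])
    t <- t + travel[j]
    rows[[length(rows) + 1L]] <- ev(t, t + p_dur[j], b, b, sites[j], 0)
    t <- t + p_dur[j]
  }
  a <- c(leg_lat[nv + 1], leg_lon[nv + 1])
  rows[[length(rows) + 1L]] <- ev(t, t + travel[nv + 1], a, home, -1, 1,
                                  d[nv + 1], speed[nv + 1])
  t <- t + travel[nv + 1]
  rows[[length(rows) + 1L]] <- ev(t, 86400, home, home, 0, 0)
  m <- do.call(rbind, rows)
  colnames(m) <- c("t0", "t1", "lat0", "lon0", "lat1", "lon1",
                   "site", "flight", "dist", "speed")
  m
}

#' Ground-truth daily features from a continuous schedule
#'
#' Computes the eight mobility features exactly from the event-level
#' schedule (flights integrated analytically, so no discretization). The
#' location-variance noise floor adds the GPS noise variance to both
#' coordinates, matching what a sensor would record for a stationary day.
#'
#' @param sched event matrix from [simulate_day_schedule()].
#' @param gps_noise_sd sensor noise used as the variance floor, meters.
#' @return named numeric vector of the eight features.
#' @export
true_features_from_schedule <- function(sched, gps_noise_sd = 10) {
  dur <- sched[, "t1"] - sched[, "t0"]
  total <- sum(dur)
  fl <- sched[, "flight"] == 1
  # time-weighted first/second moments; flights as linear segments
  m1 <- function(a, b) ifelse(fl, (a + b) / 2, a)
  m2 <- function(a, b) ifelse(fl, (a^2 + a * b + b^2) / 3, a^2)
  e_lat <- sum(dur * m1(sched[, "lat0"], sched[, "lat1"])) / total
  e_lat2 <- sum(dur * m2(sched[, "lat0"], sched[, "lat1"])) / total
  e_lon <- sum(dur * m1(sched[, "lon0"], sched[, "lon1"])) / total
  e_lon2 <- sum(dur * m2(sched[, "lon0"], sched[, "lon1"])) / total
  floor_var <- .m2deg_lat(gps_noise_sd)^2
  v <- (e_lat2 - e_lat^2) + (e_lon2 - e_lon^2) + 2 * floor_var
  dist <- sum(sched[fl, "dist"])
  trans <- sum(dur[fl]) / total
  sm <- if (any(fl)) sum(dur[fl] * sched[fl, "speed"]) / sum(dur[fl]) else 0
  sv <- if (sum(fl) > 1) {
    wm <- sm
    sum(dur[fl] * (sched[fl, "speed"] - wm)^2) / sum(dur[fl])
  } else 0
  pt <- dur[!fl]
  psite <- sched[!fl, "site"]
  tcl <- tapply(pt, psite, sum)
  p <- tcl / sum(tcl)
  ent <- -sum(p * log(p))
  nvis <- length(tcl)
  nen <- if (nvis > 1) ent / log(nvis) else 0
  hs <- sum(pt[psite == 0]) / total
  c(location_variance = log(v), speed_mean = sm, speed_variance = sv,
    total_distance = dist, transition_time = trans, n_clusters = nvis,
    normalized_entropy = nen, homestay = hs)
}

#' Advance the coupled latent mood system by one day
#'
#' Latent mood follows an AR(1) around the participant trait, driven by the
#' standardized day-to-day changes in homestay and location variance:
#' depressed mood rises with increasing homestay and falls with increasing
#' location variance; fatigue and irritability rise with increasing
#' homestay; manic mood is uncoupled. Ordinal 1-5 values are obtained by
#' thresholding (a second, noisier thresholding gives the 17:00 prompt).
#'
#' @param latent named numeric vector (fatigue, depressed, manic,
#'   irritability), current latent state.
#' @param trait participant trait (AR(1) centre).
#' @param d_hs,d_lv day-to-day change in homestay / location variance.
#' @param cfg scenario configuration (coupling coefficients, AR, noise,
#'   thresholds).
#' @return list `latent` (new state), `ordinal` (1-5 integers, both prompts
#'   as a 2 x 4 matrix).
#' @export
couple_mood_step <- function(latent, trait, d_hs, d_lv, cfg) {
  z_hs <- d_hs / cfg$dhs_sd
  z_lv <- d_lv / cfg$dlv_sd
  drive <- c(fatigue = cfg$b_hs_to_fat * z_hs,
             depressed = cfg$b_hs_to_dep * z_hs + cfg$b_lv_to_dep * z_lv,
             manic = 0,
             irritability = cfg$b_hs_to_irr * z_hs)
  eps <- stats::rnorm(4, 0, cfg$mood_noise_sd)
  new <- trait + cfg$mood_ar * (latent - trait) + drive + eps
  cut_to_ord <- function(v) findInterval(v, cfg$thresholds) + 1L
  o1 <- cut_to_ord(new + stats::rnorm(4, 0, cfg$prompt_noise_sd))
  o2 <- cut_to_ord(new + stats::rnorm(4, 0, cfg$prompt_noise_sd))
  list(latent = new, ordinal = rbind(`12:45` = o1, `17:00` = o2))
}

#' Simulate one participant's coupled mobility-mood series
#'
#' Runs the daily loop: yesterday's latent mood sets today's homestay target
#' (logit shift) and dispersal scale (log shift); the day schedule is
#' simulated; true features are computed; today's latent mood is updated from
#' the feature changes and thresholded to the two ordinal prompts.
#'
#' @param routine from [make_routine()].
#' @param cfg scenario configuration.
#' @param seed integer seed for this participant.
#' @param keep_schedules retain the event matrices (needed for GPS
#'   rendering).
#' @param start_date first local calendar date.
#' @return list: `features` (data.frame, one row per day), `ema` (both
#'   prompts, with missingness applied), `latent` (n_days x 4 matrix),
#'   `schedules` (list or NULL).
#' @export
simulate_participant <- function(routine, cfg, seed,
                                 keep_schedules = FALSE,
                                 start_date = as.Date("2020-03-01")) {
  nd <- cfg$n_days
  feats <- matrix(NA_real_, nd, 8)
  latent <- matrix(NA_real_, nd, 4)
  ords <- array(NA_integer_, c(nd, 2, 4))
  miss <- matrix(FALSE, nd, 2)
  scheds <- if (keep_schedules) vector("list", nd) else NULL
  lat_state <- routine$trait
  prev <- NULL
  for (t in seq_len(nd)) {
    res <- with_seed(derive_seed(seed, t), {
      c_dep <- lat_state["depressed"] - routine$trait["depressed"]
      c_fat <- lat_state["fatigue"] - routine$trait["fatigue"]
      c_irr <- lat_state["irritability"] - routine$trait["irritability"]
      lgt <- stats::qlogis(routine$base_homestay) +
        cfg$b_dep_to_hs * c_dep + cfg$b_fat_to_hs * c_fat +
        cfg$b_irr_to_hs * c_irr + stats::rnorm(1, 0, 0.45)
      h_t <- min(max(stats::plogis(lgt), 0.25), 0.985)
      log_g <- (cfg$b_dep_to_lv * c_dep + cfg$b_fat_to_lv * c_fat) / 2 +
        stats::rnorm(1, 0, 0.25)
      sch <- simulate_day_schedule(routine, h_t, exp(log_g))
      f <- true_features_from_schedule(sch, cfg$gps_noise_sd)
      d_hs <- if (is.null(prev)) 0 else f["homestay"] - prev["homestay"]
      d_lv <- if (is.null(prev)) 0 else
        f["location_variance"] - prev["location_variance"]
      cm <- couple_mood_step(lat_state, routine$trait, d_hs, d_lv, cfg)
      mis <- c(stats::runif(1) < cfg$ema_missing_rate,
               stats::runif(1) < min(cfg$ema_missing_rate + 0.02, 1))
      list(f = f, sch = sch, cm = cm, mis = mis)
    })
    feats[t, ] <- res$f
    lat_state <- res$cm$latent
    latent[t, ] <- lat_state
    ords[t, , ] <- res$cm$ordinal
    miss[t, ] <- res$mis
    prev <- res$f
    if (keep_schedules) scheds[[t]] <- res$sch
  }
  colnames(feats) <- c("location_variance", "speed_mean", "speed_variance",
                       "total_distance", "transition_time", "n_clusters",
                       "normalized_entropy", "homestay")
  colnames(latent) <- EMA_ITEMS
  dates <- start_date + seq_len(nd) - 1
  features <- data.frame(participant = routine$id, date = dates, feats)
  ema <- do.call(rbind, lapply(1:2, function(pr) {
    keep <- !miss[, pr]
    if (!any(keep)) return(NULL)
    data.frame(participant = routine$id, date = dates[keep],
               prompt = c("12:45", "17:00")[pr],
               fatigue = ords[keep, pr, 1], depressed = ords[keep, pr, 2],
               manic = ords[keep, pr, 3], irritability = ords[keep, pr, 4])
  }))
  list(features = features, ema = ema, latent = latent, schedules = scheds,
       dates = dates)
}

#' Render duty-cycled noisy GPS fixes from a true schedule
#'
#' Samples the continuous trajectory on the duty-cycle on-windows at
#' `burst_rate` fixes per second, adds exponentially correlated (AR(1) in
#' time) Gaussian position error with stationary SD `gps_noise_sd` and time
#' constant `noise_tau_s`, and draws lognormal accuracy values; a
#' configurable fraction of accuracies exceeds the downstream 51 m filter.
#'
#' @param sched event matrix from [simulate_day_schedule()].
#' @param cfg scenario configuration.
#' @param seed integer seed.
#' @return data.frame: `sec` (seconds of local day), `latitude`,
#'   `longitude`, `altitude`, `accuracy`.
#' @export
apply_observation_model <- function(sched, cfg, seed) {
  period <- cfg$duty_on_s + cfg$duty_off_s
  starts <- seq(0, 86399, by = period)
  step <- 1 / cfg$burst_rate
  offs <- seq(0, cfg$duty_on_s - 1e-9, by = step)
  tt <- as.vector(outer(offs, starts, "+"))
  tt <- sort(tt[tt < 86400])
  idx <- findInterval(tt, sched[, "t0"], rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  frac <- (tt - sched[idx, "t0"]) /
    pmax(sched[idx, "t1"] - sched[idx, "t0"], 1e-9)
  lat <- sched[idx, "lat0"] + frac * (sched[idx, "lat1"] - sched[idx, "lat0"])
  lon <- sched[idx, "lon0"] + frac * (sched[idx, "lon1"] - sched[idx, "lon0"])
  with_seed(seed, {
    n <- length(tt)
    lat <- lat + .m2deg_lat(.ar1_noise(tt, cfg$gps_noise_sd, cfg$noise_tau_s))
    lon <- lon + .m2deg_lon(.ar1_noise(tt, cfg$gps_noise_sd, cfg$noise_tau_s),
                            cfg$ref_lat)
    acc <- stats::rlnorm(n, cfg$acc_meanlog, cfg$acc_sdlog)
    alt <- stats::rnorm(n, 15, 3)
    data.frame(sec = tt, latitude = lat, longitude = lon,
               altitude = round(alt, 1), accuracy = acc)
  })
}

# Exponentially correlated Gaussian error sampled at irregular times.
.ar1_noise <- function(tt, sd, tau) {
  n <- length(tt)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    rho <- exp(-diff(tt) / tau)
    z <- stats::rnorm(n - 1, 0, sd)
    for (k in 2:n) e[k] <- rho[k - 1] * e[k - 1] +
        sqrt(1 - rho[k - 1]^2) * z[k - 1]
  }
  e
}

#' Lognormal accuracy meanlog for a target over-threshold fraction
#'
#' Convenience for scenario design: returns the `acc_meanlog` that makes a
#' given fraction of accuracy draws exceed `threshold` at fixed `sdlog`.
#'
#' @param frac_above target exceedance fraction.
#' @param threshold accuracy filter threshold, meters.
#' @param sdlog lognormal sdlog.
#' @return meanlog value.
#' @export
acc_meanlog_for_fraction <- function(frac_above, threshold = 51,
                                     sdlog = 0.702) {
  log(threshold) - stats::qnorm(1 - frac_above) * sdlog
}

#' Simulate a whole cohort in memory
#'
#' Runs [simulate_participant()] for every participant. The fast path for
#' statistical experiments: no GPS rendering, no disk.
#'
#' @param cfg scenario configuration.
#' @param keep_schedules retain event matrices for GPS rendering.
#' @return list: `participants` (metadata data.frame), `features` (true
#'   daily features), `ema` (both prompts), `latent`, `per_participant`.
#' @export
simulate_cohort <- function(cfg, keep_schedules = FALSE) {
  routines <- lapply(seq_len(cfg$n_participants),
                     function(i) make_routine(cfg, i))
  sims <- lapply(seq_len(cfg$n_participants), function(i)
    simulate_participant(routines[[i]], cfg,
                         derive_seed(cfg$master_seed, 2000 + i),
                         keep_schedules = keep_schedules))
  participants <- do.call(rbind, lapply(routines, function(r)
    data.frame(participant = r$id, age = r$age, sex = r$sex,
               group = r$group)))
  features <- do.call(rbind, lapply(sims, `[[`, "features"))
  ema <- do.call(rbind, lapply(sims, `[[`, "ema"))
  rownames(features) <- rownames(ema) <- NULL
  list(participants = participants, features = features, ema = ema,
       routines = routines, sims = sims, config = cfg)
}

#' Write a synthetic cohort to disk in the Beiwe dialect
#'
#' Produces a directory tree the pipeline consumes unchanged: per-participant
#' per-day GPS CSVs (six Beiwe columns, timestamps in UTC = local - 8 h),
#' `ema.csv`, `participants.csv`, ground truth under `truth/` (true daily
#' features and latent moods), and the resolved scenario as
#' `scenario.json`. Byte-identical across runs with the same configuration.
#'
#' @param cfg scenario configuration.
#' @param dir output directory (created).
#' @param utc_offset_hours local-time offset used when writing UTC
#'   timestamps. Default 8.
#' @return invisibly, the in-memory cohort from [simulate_cohort()].
#' @export
generate_cohort <- function(cfg, dir, utc_offset_hours = 8) {
  co <- simulate_cohort(cfg, keep_schedules = TRUE)
  dir.create(file.path(dir, "gps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(co$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(co$ema, file.path(dir, "ema.csv"),
                   row.names = FALSE, quote = FALSE)
  for (i in seq_along(co$sims)) {
    s <- co$sims[[i]]
    pid <- co$routines[[i]]$id
    pdir <- file.path(dir, "gps", pid)
    dir.create(pdir, showWarnings = FALSE)
    for (t in seq_along(s$schedules)) {
      fx <- apply_observation_model(s$schedules[[t]], cfg,
                                    derive_seed(cfg$master_seed, 3000 + i, t))
      t_loc <- as.POSIXct(s$dates[t], tz = "UTC") + fx$sec
      t_utc <- t_loc - utc_offset_hours * 3600
      out <- data.frame(
        timestamp = format(round(as.numeric(t_utc) * 1000),
                           scientific = FALSE),
        `UTC time` = format(t_utc, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
        latitude = sprintf("%.8f", fx$latitude),
        longitude = sprintf("%.8f", fx$longitude),
        altitude = fx$altitude,
        accuracy = sprintf("%.2f", fx$accuracy), check.names = FALSE)
      utils::write.csv(out, file.path(pdir, paste0(s$dates[t], ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  utils::write.csv(co$features, file.path(dir, "truth", "true_features.csv"),
                   row.names = FALSE, quote = FALSE)
  latent <- do.call(rbind, lapply(seq_along(co$sims), function(i)
    data.frame(participant = co$routines[[i]]$id, date = co$sims[[i]]$dates,
               co$sims[[i]]$latent)))
  utils::write.csv(latent, file.path(dir, "truth", "latent_mood.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg_out <- co$config
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(co)
}
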