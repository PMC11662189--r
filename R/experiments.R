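# Seeded validation experiments: planted-sign recovery of the lagged
# mood-mobility couplings, null calibration of the GEE delta-term test, and
# the imputation-benefit comparison. Used by the test suite and the
# acceptance script.

# the four planted pathways checked for sign recovery
.PLANTED <- data.frame(
  direction = c("feature_to_mood", "feature_to_mood",
                "mood_to_feature", "mood_to_feature"),
  outcome = c("depressed", "depressed", "location_variance", "homestay"),
  predictor = c("homestay", "location_variance", "depressed", "fatigue"),
  sign = c(1, -1, -1, 1),
  stringsAsFactors = FALSE)

.fit_planted <- function(sim) {
  analysis <- select_analysis_prompt(sim$ema)
  patients <- sim$participants$participant[
    sim$participants$group %in% c("BP", "MDD")]
  pairs <- build_day_pairs(
    sim$features[sim$features$participant %in% patients, ],
    analysis[analysis$participant %in% patients, ],
    sim$participants)
  out <- .PLANTED
  out$beta <- out$p <- NA_real_
  for (j in seq_len(nrow(out))) {
    fit <- fit_lag_model(pairs, direction = out$direction[j],
                         outcome = out$outcome[j],
                         predictor = out$predictor[j])
    out$beta[j] <- fit$delta$beta
    out$p[j] <- fit$delta$p
  }
  out
}

#' Planted-sign recovery of the bidirectional lag couplings
#'
#' Generates `n_rep` independent cohorts at the scenario defaults (with
#' planted couplings), runs the day-pair construction and the four
#' bidirectional lag-GEE models on the patient group, and checks that each
#' delta-term carries the planted sign at p < alpha. Mood coupling operates
#' on the generator's true daily features, so this isolates the statistical
#' recovery of the couplings.
#'
#' @param n_rep replicates. Default 20.
#' @param seed integer; replicate r uses a sub-seed derived from it.
#' @param cfg scenario configuration (defaults plant the couplings).
#' @param alpha significance level. Default 0.05.
#' @return list: `per_rep` (data.frame of betas/p-values), `success`
#'   (logical per replicate: all four pathways recovered), `rate`.
#' @export
experiment_sign_recovery <- function(n_rep = 20, seed = 1,
                                     cfg = scenario_config(),
                                     alpha = 0.05) {
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$master_seed <- derive_seed(seed, 100 + r)
    sim <- simulate_cohort(cfg_r)
    res <- .fit_planted(sim)
    res$rep <- r
    reps[[r]] <- res
  }
  per_rep <- do.call(rbind, reps)
  ok <- tapply(sign(per_rep$beta) == per_rep$sign & per_rep$p < alpha,
               per_rep$rep, all)
  list(per_rep = per_rep, success = as.logical(ok), rate = mean(ok))
}

#' Null calibration of the delta-term test
#'
#' With every coupling coefficient set to zero, the delta-term of each of the
#' four lag models should be declared significant at level alpha in about
#' alpha of replicates. Cohorts are scaled down (default 15 participants x
#' 60 days) so that many replicates run in minutes.
#'
#' @param n_rep replicates. Default 100.
#' @param seed integer seed.
#' @param n_participants,n_days scaled-down cohort size.
#' @param alpha level tested. Default 0.05.
#' @return list: `reject` (n_rep x 4 logical matrix), `rate_per_model`,
#'   `max_rate`.
#' @export
experiment_null_calibration <- function(n_rep = 100, seed = 1,
                                        n_participants = 15, n_days = 60,
                                        alpha = 0.05) {
  cfg <- scenario_config(
    n_participants = n_participants, n_days = n_days,
    groups = c(HC = 0, BP = ceiling(n_participants / 2),
               MDD = floor(n_participants / 2)),
    b_hs_to_dep = 0, b_hs_to_fat = 0, b_hs_to_irr = 0, b_lv_to_dep = 0,
    b_dep_to_hs = 0, b_fat_to_hs = 0, b_irr_to_hs = 0, b_dep_to_lv = 0,
    b_fat_to_lv = 0)
  reject <- matrix(NA, n_rep, nrow(.PLANTED))
  colnames(reject) <- paste(.PLANTED$outcome, .PLANTED$predictor, sep = "~")
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$master_seed <- derive_seed(seed, 500 + r)
    sim <- simulate_cohort(cfg_r)
    res <- .fit_planted(sim)
    reject[r, ] <- res$p < alpha
  }
  rates <- colMeans(reject)
  list(reject = reject, rate_per_model = rates, max_rate = max(rates))
}

#' Imputation benefit for total distance under duty cycling
#'
#' Simulates `n_days` true days, renders duty-cycled noisy fixes, runs the
#' preprocessing chain, and compares two estimates of daily total distance
#' against the continuous-trajectory truth: (a) the mean over `n_sim`
#' imputed realizations and (b) the observed-cells-only estimate. Returns
#' the mean absolute errors of both.
#'
#' @param n_days simulated days. Default 20.
#' @param seed integer seed.
#' @param cfg scenario configuration (duty cycle, noise, accuracy).
#' @param n_sim imputation realizations. Default 10.
#' @return list: `per_day` data.frame (`true`, `imputed`, `observed`),
#'   `mae_imputed`, `mae_observed`.
#' @export
experiment_imputation_benefit <- function(n_days = 20, seed = 1,
                                          cfg = scenario_config(),
                                          n_sim = 10) {
  routine <- make_routine(cfg, 1)
  rows <- vector("list", n_days)
  for (t in seq_len(n_days)) {
    sch <- simulate_day_schedule(routine, seed = derive_seed(seed, 10 + t))
    truth <- true_features_from_schedule(sch, cfg$gps_noise_sd)
    fx <- apply_observation_model(sch, cfg, derive_seed(seed, 700 + t))
    g <- classify_motion(bin_10s(fx$sec, fx$latitude, fx$longitude))
    clusters <- data.frame(cluster = 1L, lat = routine$home_lat,
                           lon = routine$home_lon, total_pause_seconds = 1,
                           is_home = TRUE)
    obs_f <- daily_features(g, clusters, coverage = mean(!is.na(g$lat)))
    reals <- impute_trajectory(g, n_sim = n_sim,
                               seed = derive_seed(seed, 900 + t))
    imp_f <- daily_features(reals, clusters, coverage = mean(!is.na(g$lat)))
    rows[[t]] <- data.frame(day = t,
                            true = unname(truth["total_distance"]),
                            imputed = imp_f$total_distance,
                            observed = obs_f$total_distance)
  }
  per_day <- do.call(rbind, rows)
  list(per_day = per_day,
       mae_imputed = mean(abs(per_day$imputed - per_day$true)),
       mae_observed = mean(abs(per_day$observed - per_day$true)))
}
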