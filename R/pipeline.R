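# End-to-end orchestration: Beiwe directory -> daily features -> weekly
# polyserial table -> bidirectional lag-model tables -> QC report.

#' Process one participant's GPS files into daily features
#'
#' Runs the full preprocessing chain: read, accuracy-filter, convert to
#' local time, bin each local day onto the 10-s grid, classify motion,
#' aggregate pauses, discover study-level clusters and the home cluster,
#' impute each day `n_sim` times, and compute realization-averaged daily
#' features.
#'
#' @param gps_paths character vector of this participant's GPS CSV files.
#' @param participant participant id used in the output.
#' @param utc_offset_hours local offset. Default 8.
#' @param accuracy_threshold accuracy filter, meters. Default 51.
#' @param n_sim imputation realizations. Default 10.
#' @param seed integer seed for the imputation.
#' @param d_max cluster radius, meters. Default 500.
#' @param coverage_floor minimum observed-cell fraction. Default 0.10.
#' @return list: `features` (one row per day), `clusters`, `qc` (retention,
#'   rejected rows, mean coverage, unimputable days).
#' @export
process_participant_gps <- function(gps_paths, participant,
                                    utc_offset_hours = 8,
                                    accuracy_threshold = 51, n_sim = 10,
                                    seed = 1, d_max = 500,
                                    coverage_floor = 0.10) {
  fixes <- read_gps_files(gps_paths, quiet = TRUE)
  n_rej <- attr(fixes, "n_rejected")
  kept <- filter_accuracy(fixes, accuracy_threshold)
  retention <- attr(kept, "retention")
  t_loc <- utc_to_local(kept$t_utc, utc_offset_hours)
  day <- local_date(t_loc)
  sec <- seconds_of_day(t_loc)
  days <- sort(unique(day))
  grids <- lapply(days, function(d) {
    sel <- day == d
    classify_motion(bin_10s(sec[sel], kept$latitude[sel],
                            kept$longitude[sel]))
  })
  names(grids) <- as.character(days)
  pauses <- do.call(rbind, lapply(grids, aggregate_pauses))
  clusters <- if (!is.null(pauses) && nrow(pauses))
    infer_home(cluster_locations(pauses, d_max = d_max), pauses)
  else cluster_locations(pauses, d_max = d_max)
  feats <- vector("list", length(days))
  unimputable <- 0L
  for (k in seq_along(days)) {
    g <- grids[[k]]
    cov <- mean(!is.na(g$lat))
    reals <- impute_trajectory(g, n_sim = n_sim,
                               seed = derive_seed(seed, k))
    if (is.null(reals)) unimputable <- unimputable + 1L
    f <- daily_features(reals, clusters, coverage = cov,
                        coverage_floor = coverage_floor)
    f <- cbind(data.frame(participant = participant, date = days[k]), f)
    feats[[k]] <- f
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  list(features = features, clusters = clusters,
       qc = data.frame(participant = participant,
                       n_fixes = nrow(fixes), n_rejected = n_rej,
                       retention = retention,
                       n_days = length(days),
                       mean_coverage = mean(features$coverage, na.rm = TRUE),
                       n_unimputable = unimputable))
}

#' Run the whole study analysis on a Beiwe-style directory
#'
#' Expects the layout written by [generate_cohort()]: `participants.csv`,
#' `ema.csv`, and `gps/<participant>/*.csv`. Produces the daily feature
#' table, the weekly polyserial correlation table (features x mood items),
#' the bidirectional day-lag GEE tables (patient group only, as in the
#' study), and a QC report.
#'
#' @param input_dir study directory.
#' @param utc_offset_hours,accuracy_threshold,n_sim,d_max,coverage_floor
#'   pipeline parameters (study defaults).
#' @param seed master seed for the imputation streams.
#' @param lag_features features entered in the lag models.
#' @return object of class `"mobimood_run"`.
#' @export
run_study <- function(input_dir, utc_offset_hours = 8,
                      accuracy_threshold = 51, n_sim = 10, d_max = 500,
                      coverage_floor = 0.10, seed = 1,
                      lag_features = c("location_variance",
                                       "normalized_entropy", "homestay")) {
  participants <- read_participants(file.path(input_dir, "participants.csv"))
  ema <- read_ema(file.path(input_dir, "ema.csv"))
  analysis <- select_analysis_prompt(ema)
  res <- lapply(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant[i]
    paths <- list.files(file.path(input_dir, "gps", pid),
                        full.names = TRUE, pattern = "\\.csv$")
    if (!length(paths))
      stop("pipeline stage gps_io failed: no GPS files for participant ",
           pid, call. = FALSE)
    process_participant_gps(paths, pid,
                            utc_offset_hours = utc_offset_hours,
                            accuracy_threshold = accuracy_threshold,
                            n_sim = n_sim, seed = derive_seed(seed, i),
                            d_max = d_max, coverage_floor = coverage_floor)
  })
  features <- do.call(rbind, lapply(res, `[[`, "features"))
  qc_gps <- do.call(rbind, lapply(res, `[[`, "qc"))

  followup <- features[, c("participant", "date")]
  missing_tbl <- ema_missing_rate(analysis, followup)
  adher <- adherence_rate(missing_tbl)

  weekly <- weekly_aggregate(features, analysis)
  cortab <- correlation_table(weekly)

  patients <- participants$participant[participants$group %in% c("BP", "MDD")]
  pairs <- build_day_pairs(features[features$participant %in% patients, ],
                           analysis[analysis$participant %in% patients, ],
                           participants, feature_vars = lag_features)
  lag_fm <- lag_table(pairs, direction = "feature_to_mood",
                      outcomes = EMA_ITEMS, predictors = lag_features)
  lag_mf <- lag_table(pairs, direction = "mood_to_feature",
                      outcomes = lag_features, predictors = EMA_ITEMS)

  structure(list(features = features, weekly = weekly,
                 correlations = cortab, pairs = pairs,
                 lag_feature_to_mood = lag_fm, lag_mood_to_feature = lag_mf,
                 qc = list(gps = qc_gps, ema_missing = missing_tbl,
                           adherence = adher,
                           n_pairs = nrow(pairs),
                           n_pairs_dropped = attr(pairs, "n_dropped"))),
            class = "mobimood_run")
}

#' Weekly polyserial correlation table (features x mood items)
#'
#' @param weekly participant-level weekly table from [weekly_aggregate()].
#' @param features,items variables to correlate.
#' @return data.frame: one row per feature-item pair with `rho`, `p`, `n`.
#' @export
correlation_table <- function(weekly, features = GPS_FEATURES,
                              items = EMA_ITEMS) {
  out <- list()
  for (f in intersect(features, names(weekly))) {
    for (it in intersect(items, names(weekly))) {
      ok <- stats::complete.cases(weekly[[f]], weekly[[it]])
      row <- data.frame(feature = f, item = it, rho = NA_real_,
                        p = NA_real_, n = sum(ok))
      if (sum(ok) >= 5 && length(unique(weekly[[it]][ok])) >= 2) {
        ps <- polyserial_cor(weekly[[f]][ok], weekly[[it]][ok])
        row$rho <- ps$rho; row$p <- ps$p_value
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Fit a block of day-lag models (one table of the results layout)
#'
#' @param pairs day-pair table.
#' @param direction `"feature_to_mood"` or `"mood_to_feature"`.
#' @param outcomes day-2 outcome variables.
#' @param predictors lagged-change predictors.
#' @return data.frame: one row per (outcome, predictor, term) with `beta`,
#'   `se`, `p`.
#' @export
lag_table <- function(pairs, direction, outcomes, predictors) {
  out <- list()
  for (pred in predictors) {
    for (y in outcomes) {
      fit <- fit_lag_model(pairs, direction = direction, outcome = y,
                           predictor = pred)
      tb <- fit$table
      out[[length(out) + 1L]] <- data.frame(
        direction = direction, outcome = y, predictor = pred,
        term = rownames(tb), beta = tb[, "Estimate"],
        se = tb[, "Robust SE"], p = tb[, "Pr(>|z|)"],
        alpha = fit$alpha, n_pairs = fit$n_pairs, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' @export
print.mobimood_run <- function(x, ...) {
  cat("mobimood study run\n")
  cat(sprintf("  %d participant-days of features, %d weekly rows, %d day pairs\n",
              nrow(x$features), nrow(x$weekly), x$qc$n_pairs))
  cat(sprintf("  EMA adherence: %.1f%% (%d/%d person-days)\n",
              x$qc$adherence$adherence_pct, x$qc$adherence$answered,
              x$qc$adherence$person_days))
  sig <- x$correlations[!is.na(x$correlations$p) & x$correlations$p < .05, ]
  if (nrow(sig)) {
    cat("  weekly correlations with p < .05:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s ~ %s: rho = %.3f (p = %.3g)\n", sig$feature[i],
                  sig$item[i], sig$rho[i], sig$p[i]))
  }
  invisible(x)
}

#' Write a run's result tables as CSV
#'
#' @param run `mobimood_run` object.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(dir, "daily_features.csv"),
                   row.names = FALSE)
  utils::write.csv(run$correlations, file.path(dir, "weekly_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$lag_feature_to_mood,
                   file.path(dir, "lag_feature_to_mood.csv"),
                   row.names = FALSE)
  utils::write.csv(run$lag_mood_to_feature,
                   file.path(dir, "lag_mood_to_feature.csv"),
                   row.names = FALSE)
  utils::write.csv(run$qc$gps, file.path(dir, "qc_gps.csv"),
                   row.names = FALSE)
  utils::write.csv(run$qc$ema_missing, file.path(dir, "qc_ema_missing.csv"),
                   row.names = FALSE)
  invisible(dir)
}
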