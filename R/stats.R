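# Statistics layer: weekly polyserial feature-mood correlation, bidirectional
# day-lagged GEE models, and Fisher-z power / sample-size calculations.

GPS_FEATURES <- c("location_variance", "speed_mean", "speed_variance",
                  "total_distance", "transition_time", "n_clusters",
                  "homestay", "normalized_entropy")

#' Weekly participant-level aggregation of features and mood
#'
#' For the cross-sectional correlation each participant contributes the mean
#' of each GPS feature and the rounded mean mood category (ordinal 1-5) over
#' one 7-day window, by default the participant's first window with at least
#' `min_days` valid days in both series. Participants without such a window
#' are excluded (counted in the `excluded` attribute).
#'
#' @param features daily feature table (`participant`, `date`, feature
#'   columns).
#' @param ema analysis mood series from [select_analysis_prompt()].
#' @param min_days minimum valid days in the window for both series.
#'   Default 4.
#' @param window window length in days. Default 7.
#' @param all_weeks average over all qualifying windows instead of the first.
#' @return data.frame: one row per retained participant with weekly feature
#'   means and the four weekly ordinal moods.
#' @export
weekly_aggregate <- function(features, ema, min_days = 4, window = 7,
                             all_weeks = FALSE) {
  out <- list(); excluded <- character(0)
  for (p in unique(features$participant)) {
    f <- features[features$participant == p, ]
    e <- ema[ema$participant == p, ]
    if (!nrow(f) || !nrow(e)) { excluded <- c(excluded, p); next }
    d0 <- min(c(f$date, e$date))
    d1 <- max(c(f$date, e$date))
    wk_rows <- list()
    for (ws in seq(from = as.numeric(d0), to = as.numeric(d1), by = window)) {
      days <- as.Date(ws + 0:(window - 1), origin = "1970-01-01")
      fw <- f[f$date %in% days & !is.na(f$location_variance), ]
      ew <- e[e$date %in% days & rowSums(!is.na(e[, EMA_ITEMS])) > 0, ]
      if (nrow(fw) >= min_days && nrow(ew) >= min_days) {
        row <- data.frame(participant = p)
        for (v in intersect(GPS_FEATURES, names(fw)))
          row[[v]] <- mean(fw[[v]], na.rm = TRUE)
        for (it in EMA_ITEMS)
          row[[it]] <- round(mean(ew[[it]], na.rm = TRUE))
        wk_rows[[length(wk_rows) + 1L]] <- row
        if (!all_weeks) break
      }
    }
    if (!length(wk_rows)) { excluded <- c(excluded, p); next }
    wk <- do.call(rbind, wk_rows)
    if (nrow(wk) > 1L) {
      agg <- wk[1, , drop = FALSE]
      for (v in setdiff(names(wk), c("participant", EMA_ITEMS)))
        agg[[v]] <- mean(wk[[v]])
      for (it in EMA_ITEMS) agg[[it]] <- round(mean(wk[[it]]))
      wk <- agg
    }
    out[[length(out) + 1L]] <- wk
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant = character(0))
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Polyserial correlation between a continuous and an ordinal variable
#'
#' Two-step estimator of the correlation between x and the latent standard
#' normal variable assumed to underlie the ordinal y: thresholds are fixed at
#' the inverse-normal cumulative proportions of the ordinal margin, then rho
#' of the latent bivariate normal is estimated by maximum likelihood of the
#' conditional ordinal probabilities given standardized x. The two-sided
#' p-value comes from the large-sample (observed-information) standard error
#' of rho.
#'
#' @param x numeric vector.
#' @param y ordinal vector (integer-coded; any number of levels >= 2).
#' @return object of class `"polyserial_cor"`: `rho`, `se`, `p_value`, `n`,
#'   `thresholds`.
#' @export
polyserial_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  lev <- sort(unique(y))
  if (length(lev) < 2)
    return(structure(list(rho = NA_real_, se = NA_real_, p_value = NA_real_,
                          n = n, thresholds = numeric(0),
                          reason = "ordinal variable is constant"),
                     class = "polyserial_cor"))
  z <- (x - mean(x)) / stats::sd(x)
  yi <- match(y, lev)
  cum <- cumsum(tabulate(yi, length(lev))) / n
  tau <- stats::qnorm(cum[-length(cum)])        # K-1 interior thresholds
  lo <- c(-Inf, tau)[yi]
  hi <- c(tau, Inf)[yi]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-9)
  rho <- opt$minimum
  h <- 1e-4
  d2 <- (nll(min(rho + h, 0.999)) - 2 * nll(rho) +
           nll(max(rho - h, -0.999))) / h^2
  se <- if (is.finite(d2) && d2 > 0) sqrt(1 / d2) else NA_real_
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(rho / se))
  structure(list(rho = rho, se = se, p_value = p, n = n, thresholds = tau),
            class = "polyserial_cor")
}

#' @export
print.polyserial_cor <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("Polyserial correlation: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Polyserial correlation: rho = %.3f (SE %.3f, p = %.3g, n = %d)\n",
                x$rho, x$se, x$p_value, x$n))
  }
  invisible(x)
}

#' Build the consecutive-day pair table for the lag models
#'
#' One row per pair of consecutive calendar days within a participant,
#' carrying day-1 and day-2 levels and day-2 minus day-1 changes of each
#' feature and mood item, plus age and sex. Pairs with any required value
#' missing are dropped; the dropped count is reported via attribute
#' `n_dropped`.
#'
#' @param features daily feature table.
#' @param ema analysis mood series.
#' @param participants metadata table (`participant`, `age`, `sex`, `group`).
#' @param feature_vars,mood_vars variables to carry (defaults: the three
#'   lag-model features and all four moods).
#' @return data.frame of day pairs.
#' @export
build_day_pairs <- function(features, ema, participants,
                            feature_vars = c("location_variance",
                                             "normalized_entropy", "homestay"),
                            mood_vars = EMA_ITEMS) {
  m <- merge(features, ema, by = c("participant", "date"), all = TRUE)
  m <- merge(m, participants, by = "participant")
  m <- m[order(m$participant, m$date), ]
  out <- list(); dropped <- 0L
  for (p in unique(m$participant)) {
    s <- m[m$participant == p, ]
    nxt <- match(s$date + 1, s$date)
    has <- which(!is.na(nxt))
    if (!length(has)) next
    i1 <- has; i2 <- nxt[has]
    pr <- data.frame(participant = p, day1 = s$date[i1], day2 = s$date[i2],
                     age = s$age[i1], sex = s$sex[i1], group = s$group[i1],
                     day_index = as.numeric(s$date[i1]))
    for (v in feature_vars) {
      pr[[paste0(v, "_1")]] <- s[[v]][i1]
      pr[[paste0(v, "_2")]] <- s[[v]][i2]
      pr[[paste0("d_", v)]] <- s[[v]][i2] - s[[v]][i1]
    }
    for (v in mood_vars) {
      pr[[paste0(v, "_1")]] <- s[[v]][i1]
      pr[[paste0(v, "_2")]] <- s[[v]][i2]
      pr[[paste0("d_", v)]] <- s[[v]][i2] - s[[v]][i1]
    }
    keep <- stats::complete.cases(pr)
    dropped <- dropped + sum(!keep)
    out[[length(out) + 1L]] <- pr[keep, , drop = FALSE]
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(res)) stop("no day pairs could be formed", call. = FALSE)
  rownames(res) <- NULL
  attr(res, "n_dropped") <- dropped
  res
}

#' Fit one bidirectional day-lag model
#'
#' The feature-to-mood direction regresses the day-2 mood on the day-1-to-
#' day-2 feature change, age, sex, and the day-1 feature level; the
#' mood-to-feature direction regresses the day-2 feature on the mood change,
#' age, sex, and the day-1 mood level. Fitting is by [gee_ar1()] with the
#' participant as cluster, day index as AR(1) time, and robust SEs.
#'
#' @param pairs day-pair table from [build_day_pairs()].
#' @param direction `"feature_to_mood"` or `"mood_to_feature"`.
#' @param outcome the day-2 outcome variable (mood item or feature name,
#'   without the `_2` suffix).
#' @param predictor the lagged-change predictor (feature or mood name).
#' @param corstr working correlation, passed to [gee_ar1()].
#' @return object of class `"lag_fit"` wrapping the `gee_ar1` fit with the
#'   delta-term summary pulled out.
#' @export
fit_lag_model <- function(pairs, direction = c("feature_to_mood",
                          "mood_to_feature"), outcome, predictor,
                          corstr = "ar1") {
  direction <- match.arg(direction)
  if (nrow(pairs) < 10 || length(unique(pairs$participant)) < 2)
    stop("need at least 2 participants and 10 day pairs", call. = FALSE)
  dterm <- paste0("d_", predictor)
  lag1 <- paste0(predictor, "_1")
  fml <- stats::as.formula(paste0(outcome, "_2 ~ ", dterm,
                                  " + age + sex + ", lag1))
  fit <- gee_ar1(fml, pairs, id = "participant", time = "day_index",
                 corstr = corstr)
  if (!fit$converged)
    warning("GEE iteration did not converge for outcome ", outcome)
  s <- summary(fit)$coefficients
  structure(list(direction = direction, outcome = outcome,
                 predictor = predictor, fit = fit, table = s,
                 delta = list(beta = s[dterm, "Estimate"],
                              se = s[dterm, "Robust SE"],
                              p = s[dterm, "Pr(>|z|)"]),
                 alpha = fit$alpha, n_pairs = fit$n_obs,
                 n_participants = fit$n_clusters),
            class = "lag_fit")
}

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("Day-lag model (%s): %s_2 on d_%s + age + sex + %s_1\n",
              x$direction, x$outcome, x$predictor, x$predictor))
  cat(sprintf("  %d participants, %d pairs, AR(1) alpha = %.3f\n",
              x$n_participants, x$n_pairs, x$alpha))
  cat(sprintf("  delta-term beta = %.4f (robust SE %.4f, p = %.3g)\n",
              x$delta$beta, x$delta$se, x$delta$p))
  invisible(x)
}

#' Required sample size for detecting a correlation (Fisher z)
#'
#' Number of participants needed to detect a correlation `rho` at two-sided
#' level `alpha` with the given power, from the normal approximation to the
#' Fisher z transform: n = ((z_{1-alpha/2} + z_power) / atanh(rho))^2 + 3,
#' rounded to the nearest integer (the convention that reproduces the
#' standard published values, e.g. 29 at rho = 0.5, power .80).
#'
#' @param rho target correlation, 0 < |rho| < 1.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size.
#' @export
fisher_required_n <- function(rho, alpha = 0.05, power = 0.80) {
  stopifnot(abs(rho) > 0, abs(rho) < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(round(((za + zb) / atanh(abs(rho)))^2 + 3))
}

#' Achieved power for a correlation test at sample size n (Fisher z)
#'
#' power = Phi(atanh(|rho|) * sqrt(n - 3) - z_{1-alpha/2}), the two-sided
#' test's power ignoring the negligible far tail.
#'
#' @param rho correlation.
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
fisher_power <- function(rho, n, alpha = 0.05) {
  stopifnot(n >= 4)
  stats::pnorm(atanh(abs(rho)) * sqrt(n - 3) - stats::qnorm(1 - alpha / 2))
}
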