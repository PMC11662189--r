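# Twice-daily 4-item ordinal mood EMA: analysis-series reduction,
# between-prompt agreement (ICC), and missingness accounting.

EMA_ITEMS <- c("fatigue", "depressed", "manic", "irritability")

#' Reduce the twice-daily EMA to the analysis series
#'
#' The study analyses the 12:45 responses (the prompt with the higher
#' completion rate); when the 12:45 record is absent for a date the date is
#' missing — there is no fallback to the 17:00 prompt. Duplicate records for
#' the same participant-date-prompt keep the first by load order, with a
#' message.
#'
#' @param ema data.frame from [read_ema()].
#' @param analysis_prompt prompt label kept for analysis. Default `"12:45"`.
#' @return data.frame with one row per participant-date holding the four
#'   items (NA when the analysis prompt was unanswered).
#' @export
select_analysis_prompt <- function(ema, analysis_prompt = "12:45") {
  key <- paste(ema$participant, ema$date, ema$prompt)
  dup <- duplicated(key)
  if (any(dup)) {
    message("select_analysis_prompt: dropping ", sum(dup),
            " duplicate record(s), keeping first by load order")
    ema <- ema[!dup, , drop = FALSE]
  }
  out <- ema[ema$prompt == analysis_prompt,
             c("participant", "date", EMA_ITEMS), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-prompt agreement of one mood item
#'
#' Intraclass correlation between the 12:45 and 17:00 responses of one item:
#' two-way mixed effects, absolute agreement, single measures (ICC(A,1)),
#' computed within each participant over dates with both prompts answered and
#' then averaged across participants. With dates as rows and the k = 2
#' prompts as columns,
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#' Being an absolute-agreement form, it penalises a constant offset between
#' the prompts (unlike consistency-type ICCs).
#'
#' @param ema data.frame from [read_ema()] (both prompts).
#' @param item one of `"fatigue"`, `"depressed"`, `"manic"`, `"irritability"`.
#' @param prompts the two prompt labels.
#' @return list with `icc` (NA when no participant has >= 2 complete dates),
#'   `n_pairs` (complete date-pairs used), `per_participant`.
#' @export
icc_between_prompts <- function(ema, item = EMA_ITEMS,
                                prompts = c("12:45", "17:00")) {
  item <- match.arg(item)
  per <- c(); used <- 0L
  for (p in unique(ema$participant)) {
    sub <- ema[ema$participant == p, ]
    a <- sub[sub$prompt == prompts[1], c("date", item)]
    b <- sub[sub$prompt == prompts[2], c("date", item)]
    m <- merge(a, b, by = "date")
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) >= 2L) {
      v <- .icc_a1(as.matrix(m[, -1]))
      if (!is.na(v)) {
        per <- c(per, stats::setNames(v, p))
        used <- used + nrow(m)
      }
    }
  }
  list(icc = if (length(per)) mean(per) else NA_real_,
       n_pairs = used, per_participant = per)
}

# ICC(A,1): two-way ANOVA mean squares on an n x k matrix (rows = dates).
.icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (den <= 0) return(NA_real_)
  (msr - mse) / den
}

#' Per-participant EMA missingness over the follow-up calendar
#'
#' Fraction of each participant's follow-up days without an analysis-prompt
#' response (all four items missing counts as unanswered; a date absent from
#' the analysis series counts as unanswered).
#'
#' @param analysis data.frame from [select_analysis_prompt()].
#' @param followup data.frame with columns `participant`, `date` listing every
#'   follow-up day per participant.
#' @return data.frame `participant`, `n_days`, `n_missing`, `missing_rate`.
#' @export
ema_missing_rate <- function(analysis, followup) {
  answered <- analysis[rowSums(!is.na(analysis[, EMA_ITEMS])) > 0, ]
  key <- paste(answered$participant, answered$date)
  out <- do.call(rbind, lapply(split(followup, followup$participant),
    function(fu) {
      hit <- paste(fu$participant, fu$date) %in% key
      data.frame(participant = fu$participant[1], n_days = nrow(fu),
                 n_missing = sum(!hit), missing_rate = mean(!hit))
    }))
  rownames(out) <- NULL
  out
}

#' Synthetic adherence fixture at the study's printed counts
#'
#' Builds a deterministic synthetic follow-up calendar of 5137 person-days
#' over 38 participants with 334 unanswered analysis prompts (4803
#' answered), writes the answered prompts as an EMA CSV, and returns the
#' follow-up index. Exists so the QC counting path can be exercised at the
#' exact published denominators without any participant data.
#'
#' @param ema_csv path the EMA CSV is written to.
#' @return list: `ema_csv` (the path), `followup` (data.frame `participant`,
#'   `date`), `answered`, `person_days`.
#' @export
adherence_fixture <- function(ema_csv = tempfile(fileext = ".csv")) {
  n_days <- rep(c(136L, 135L), c(7L, 31L))  # sums to 5137
  n_miss <- rep(c(8L, 9L), c(8L, 30L))      # sums to 334
  rows <- list(); fu <- list()
  for (i in seq_len(38)) {
    pid <- sprintf("P%02d", i)
    dates <- as.Date("2020-03-01") + seq_len(n_days[i]) - 1
    fu[[i]] <- data.frame(participant = pid, date = dates)
    miss_at <- round(seq(1, n_days[i], length.out = n_miss[i]))
    ans <- dates[-miss_at]
    rows[[i]] <- data.frame(participant = pid, date = ans, prompt = "12:45",
                            fatigue = 2L, depressed = 2L, manic = 1L,
                            irritability = 1L)
  }
  ema <- do.call(rbind, rows)
  utils::write.csv(ema, ema_csv, row.names = FALSE, quote = FALSE)
  followup <- do.call(rbind, fu)
  list(ema_csv = ema_csv, followup = followup,
       answered = nrow(ema), person_days = nrow(followup))
}

#' Cohort adherence rate
#'
#' Proportion of follow-up person-days with a completed EMA mood assessment,
#' as a percentage over the whole sample.
#'
#' @param missing_tbl output of [ema_missing_rate()].
#' @return list with `answered`, `person_days`, `adherence_pct`.
#' @export
adherence_rate <- function(missing_tbl) {
  pd <- sum(missing_tbl$n_days)
  ans <- pd - sum(missing_tbl$n_missing)
  list(answered = ans, person_days = pd, adherence_pct = 100 * ans / pd)
}
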