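#' Read Beiwe-style raw GPS files
#'
#' Loads one or more hourly GPS chunk files (CSV), validates each row,
#' concatenates across files and sorts by UTC timestamp. Beiwe exports one
#' file per hour with six columns: `timestamp` (epoch milliseconds),
#' `UTC time` (ISO-8601), `latitude`, `longitude`, `altitude`, `accuracy`.
#' Either time column may be used; epoch milliseconds take precedence when
#' both parse.
#'
#' Malformed rows (unparseable timestamp, latitude outside \[-90, 90\],
#' longitude outside \[-180, 180\], negative or missing accuracy) are
#' rejected row-wise, counted, and reported via the `"n_rejected"` attribute
#' and a message; they are never silently dropped. A missing required column
#' is a hard error naming the column.
#'
#' @param paths character vector of file paths. May be empty.
#' @param column_map named character vector mapping the canonical names
#'   `timestamp`, `utc_time`, `latitude`, `longitude`, `altitude`, `accuracy`
#'   to the header names actually present in the files.
#' @param quiet suppress the per-file rejection message.
#' @return A data.frame of accepted fixes with columns `t_utc` (POSIXct, UTC),
#'   `latitude`, `longitude`, `altitude`, `accuracy`, sorted by `t_utc`
#'   (ties kept in load order), with attribute `n_rejected`.
#' @export
read_gps_files <- function(paths,
                           column_map = c(timestamp = "timestamp",
                                          utc_time = "UTC time",
                                          latitude = "latitude",
                                          longitude = "longitude",
                                          altitude = "altitude",
                                          accuracy = "accuracy"),
                           quiet = FALSE) {
  empty <- data.frame(t_utc = as.POSIXct(numeric(0), origin = "1970-01-01",
                                         tz = "UTC"),
                      latitude = numeric(0), longitude = numeric(0),
                      altitude = numeric(0), accuracy = numeric(0))
  if (length(paths) == 0L) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  pieces <- vector("list", length(paths))
  n_rej <- 0L
  for (i in seq_along(paths)) {
    raw <- utils::read.csv(paths[i], check.names = FALSE,
                           stringsAsFactors = FALSE)
    for (canon in c("latitude", "longitude", "altitude", "accuracy")) {
      if (!column_map[[canon]] %in% names(raw))
        stop("GPS file ", paths[i], " is missing required column '",
             column_map[[canon]], "'", call. = FALSE)
    }
    has_ts <- column_map[["timestamp"]] %in% names(raw)
    has_utc <- column_map[["utc_time"]] %in% names(raw)
    if (!has_ts && !has_utc)
      stop("GPS file ", paths[i], " is missing required column '",
           column_map[["timestamp"]], "' (or '", column_map[["utc_time"]],
           "')", call. = FALSE)
    t_utc <- rep(as.POSIXct(NA, tz = "UTC"), nrow(raw))
    if (has_ts)
      t_utc <- .parse_epoch_ms(raw[[column_map[["timestamp"]]]])
    if (has_utc) {
      need <- is.na(t_utc)
      if (any(need))
        t_utc[need] <- .parse_iso8601(raw[[column_map[["utc_time"]]]][need])
    }
    lat <- suppressWarnings(as.numeric(raw[[column_map[["latitude"]]]]))
    lon <- suppressWarnings(as.numeric(raw[[column_map[["longitude"]]]]))
    alt <- suppressWarnings(as.numeric(raw[[column_map[["altitude"]]]]))
    acc <- suppressWarnings(as.numeric(raw[[column_map[["accuracy"]]]]))
    ok <- !is.na(t_utc) &
      !is.na(lat) & lat >= -90 & lat <= 90 &
      !is.na(lon) & lon >= -180 & lon <= 180 &
      !is.na(acc) & acc >= 0
    n_bad <- sum(!ok)
    if (n_bad > 0L && !quiet)
      message("read_gps_files: rejected ", n_bad, " malformed row",
              if (n_bad > 1L) "s", " in ", basename(paths[i]))
    n_rej <- n_rej + n_bad
    pieces[[i]] <- data.frame(t_utc = t_utc[ok], latitude = lat[ok],
                              longitude = lon[ok], altitude = alt[ok],
                              accuracy = acc[ok])
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$t_utc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

.parse_epoch_ms <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  # epoch-ms values are ~1e12; plain epoch-seconds (~1e9) are also accepted
  v <- ifelse(!is.na(v) & abs(v) >= 1e11, v / 1000, v)
  v[!is.na(v) & abs(v) < 1e8] <- NA  # too small to be a modern epoch
  as.POSIXct(v, origin = "1970-01-01", tz = "UTC")
}

.parse_iso8601 <- function(x) {
  x <- as.character(x)
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  retry <- is.na(out)
  if (any(retry))
    out[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M", tz = "UTC"))
  out
}

#' Write GPS fixes back to the Beiwe CSV dialect
#'
#' Inverse of [read_gps_files()]: writes the six canonical columns with
#' `timestamp` as epoch milliseconds and `UTC time` as ISO-8601, so that a
#' read/write round trip preserves accepted rows exactly.
#'
#' @param fixes data.frame as returned by [read_gps_files()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps <- function(fixes, path) {
  out <- data.frame(
    timestamp = format(round(as.numeric(fixes$t_utc) * 1000), scientific = FALSE),
    `UTC time` = format(fixes$t_utc, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    latitude = fixes$latitude, longitude = fixes$longitude,
    altitude = fixes$altitude, accuracy = fixes$accuracy,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert UTC instants to local study time
#'
#' The study clock runs a fixed number of hours ahead of UTC (Taiwan is
#' UTC+8); all daily aggregation uses local calendar days. A fixed offset is
#' used deliberately — no daylight-saving rules.
#'
#' @param t_utc POSIXct vector (UTC).
#' @param offset_hours integer hours ahead of UTC. Default 8.
#' @return POSIXct vector shifted by the offset (still carrying tz "UTC";
#'   interpret clock fields as local).
#' @export
utc_to_local <- function(t_utc, offset_hours = 8) {
  t_utc + offset_hours * 3600
}

#' Local calendar date of a local instant
#' @param t_local POSIXct as returned by [utc_to_local()].
#' @return Date vector.
#' @export
local_date <- function(t_local) {
  as.Date(t_local, tz = "UTC")
}

#' Seconds since local midnight
#' @param t_local POSIXct as returned by [utc_to_local()].
#' @return numeric seconds in \[0, 86400).
#' @export
seconds_of_day <- function(t_local) {
  as.numeric(t_local) - as.numeric(as.POSIXct(local_date(t_local), tz = "UTC"))
}

#' Read an EMA response table
#'
#' Expects columns `participant`, `date` (local, YYYY-MM-DD), `prompt`
#' (`"12:45"` or `"17:00"`), and the four mood items `fatigue`, `depressed`,
#' `manic`, `irritability` (integers 1-5 or blank). Values outside 1-5 are
#' set missing with a count reported via attribute `n_invalid`.
#'
#' @param path CSV path.
#' @return data.frame with one row per participant-date-prompt.
#' @export
read_ema <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "date", "prompt", "fatigue", "depressed",
            "manic", "irritability")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("EMA file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw$date <- as.Date(raw$date)
  n_invalid <- 0L
  for (item in c("fatigue", "depressed", "manic", "irritability")) {
    v <- suppressWarnings(as.numeric(raw[[item]]))
    bad <- !is.na(v) & !(v %in% 1:5)
    n_invalid <- n_invalid + sum(bad)
    v[bad] <- NA
    raw[[item]] <- v
  }
  raw <- raw[, need]
  attr(raw, "n_invalid") <- n_invalid
  raw
}

#' Read the participant metadata table
#'
#' Columns: `participant`, `age` (years), `sex` (1 = male, 0 = female),
#' `group` (one of HC, BP, MDD).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_participants <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "age", "sex", "group")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("participant file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !out$group %in% c("HC", "BP", "MDD")
  if (any(bad))
    stop("unknown diagnosis group(s): ",
         paste(unique(out$group[bad]), collapse = ", "), call. = FALSE)
  out[, need]
}
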