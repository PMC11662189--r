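# Eight daily mobility features from imputed trajectories, with study-level
# location clustering and home inference.

#' Discover location clusters from pause events
#'
#' Duration-weighted centroid clustering of pause-event centroids, pooled over
#' the whole study for one participant so that homestay and entropy are
#' comparable across days. The number of clusters k is increased from 1 until
#' every pause lies within `d_max` meters of its assigned centroid.
#' Initialization is deterministic (farthest-point seeding from the
#' highest-weight pause), followed by weighted Lloyd iterations, so the same
#' pauses always give the same clusters.
#'
#' @param pauses data.frame of pause events (`lat`, `lon`, `duration`),
#'   typically pooled across all of a participant's days.
#' @param d_max maximum pause-to-centroid distance, meters. Default 500.
#' @param k_max safety cap on the number of clusters.
#' @return data.frame of clusters: `cluster`, `lat`, `lon`,
#'   `total_pause_seconds`, `is_home` (all FALSE; see [infer_home()]), or an
#'   empty data.frame with a warning when there are no pauses.
#' @export
cluster_locations <- function(pauses, d_max = 500, k_max = 50) {
  empty <- data.frame(cluster = integer(0), lat = numeric(0),
                      lon = numeric(0), total_pause_seconds = numeric(0),
                      is_home = logical(0))
  if (is.null(pauses) || nrow(pauses) == 0L) {
    warning("no pause events; returning empty cluster set")
    return(empty)
  }
  w <- pauses$duration
  for (k in seq_len(min(k_max, nrow(pauses)))) {
    fit <- .wkmeans(pauses$lat, pauses$lon, w, k)
    if (max(fit$dist) <= d_max || k == min(k_max, nrow(pauses))) {
      tot <- vapply(seq_len(k), function(j) sum(w[fit$assign == j]), 0)
      keep <- tot > 0
      out <- data.frame(cluster = seq_len(sum(keep)),
                        lat = fit$lat[keep], lon = fit$lon[keep],
                        total_pause_seconds = tot[keep], is_home = FALSE)
      attr(out, "assign") <- match(fit$assign, which(keep))
      return(out)
    }
  }
  empty
}

# Weighted Lloyd k-means on lat/lon with Mercator metric; deterministic
# farthest-point init.
.wkmeans <- function(lat, lon, w, k, max_iter = 50) {
  n <- length(lat)
  centers <- which.max(w)
  while (length(centers) < k) {
    dmin <- rep(Inf, n)
    for (c in centers)
      dmin <- pmin(dmin, mercator_distance(lat, lon, lat[c], lon[c]))
    centers <- c(centers, which.max(dmin))
  }
  clat <- lat[centers]; clon <- lon[centers]
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    dm <- vapply(seq_len(k),
                 function(j) mercator_distance(lat, lon, clat[j], clon[j]),
                 numeric(n))
    dm <- matrix(dm, nrow = n)
    new_assign <- max.col(-dm, ties.method = "first")
    if (it > 1L && all(new_assign == assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      in_j <- assign == j
      if (any(in_j)) {
        clat[j] <- sum(w[in_j] * lat[in_j]) / sum(w[in_j])
        clon[j] <- sum(w[in_j] * lon[in_j]) / sum(w[in_j])
      }
    }
  }
  dist <- mercator_distance(lat, lon, clat[assign], clon[assign])
  list(lat = clat, lon = clon, assign = assign, dist = dist)
}

#' Assign pause events to their nearest cluster
#' @param pauses pause-event data.frame.
#' @param clusters cluster data.frame from [cluster_locations()].
#' @return integer vector of cluster ids.
#' @export
assign_clusters <- function(pauses, clusters) {
  if (nrow(clusters) == 0L || nrow(pauses) == 0L)
    return(integer(nrow(pauses)))
  dm <- vapply(seq_len(nrow(clusters)),
               function(j) mercator_distance(pauses$lat, pauses$lon,
                                             clusters$lat[j], clusters$lon[j]),
               numeric(nrow(pauses)))
  dm <- matrix(dm, nrow = nrow(pauses))
  max.col(-dm, ties.method = "first")
}

#' Flag the home cluster
#'
#' Home is the cluster holding the largest summed pause time in the nocturnal
#' 00:00-06:00 local window over the whole study; ties (and the no-nocturnal-
#' pause fallback, which is warned about) go to the largest all-day pause
#' time.
#'
#' @param clusters cluster data.frame from [cluster_locations()].
#' @param pauses the same pause events used for clustering, with `t_begin`,
#'   `t_end` in seconds of local day and a `cluster` assignment column (or
#'   pass `assign`).
#' @param assign optional integer vector from [assign_clusters()].
#' @param night_window seconds-of-day window counted as nocturnal.
#' @return `clusters` with exactly one row flagged `is_home`.
#' @export
infer_home <- function(clusters, pauses,
                       assign = assign_clusters(pauses, clusters),
                       night_window = c(0, 6 * 3600)) {
  stopifnot(nrow(clusters) > 0L)
  night <- pmax(0, pmin(pauses$t_end, night_window[2]) -
                  pmax(pauses$t_begin, night_window[1]))
  night_by <- vapply(seq_len(nrow(clusters)),
                     function(j) sum(night[assign == j]), 0)
  allday_by <- vapply(seq_len(nrow(clusters)),
                      function(j) sum(pauses$duration[assign == j]), 0)
  if (all(night_by == 0)) {
    warning("no nocturnal pause time; falling back to largest all-day cluster")
    home <- which.max(allday_by)
  } else {
    best <- which(night_by == max(night_by))
    home <- if (length(best) > 1L) best[which.max(allday_by[best])] else best
  }
  clusters$is_home <- FALSE
  clusters$is_home[home] <- TRUE
  clusters
}

#' Eight daily mobility features for one participant-day
#'
#' Computes the features on each imputed realization and averages over
#' realizations:
#' \itemize{
#'   \item `location_variance`: log(var(lat) + var(lon)) over all points of
#'     the day (degrees^2 inside the log);
#'   \item `speed_mean`, `speed_variance`: over moving cells only, speed =
#'     10-s displacement / 10 s (m/s);
#'   \item `total_distance`: sum of adjacent 10-s displacements over steps
#'     adjacent to a moving cell, meters (steps between two pause cells are
#'     sub-threshold sensor jitter and are not travel);
#'   \item `transition_time`: moving cells / non-missing cells;
#'   \item `n_clusters`: distinct study-level clusters visited (pause time
#'     > 0) that day;
#'   \item `normalized_entropy`: Shannon entropy of the pause-time
#'     distribution over clusters divided by log(clusters visited); 0 when
#'     at most one cluster is visited;
#'   \item `homestay`: pause time in the home cluster / total non-missing
#'     time.
#' }
#' Days whose observed coverage is below `coverage_floor` and that could not
#' be imputed are returned with `NA` features and a `reason` code.
#'
#' @param realizations list of complete day grids from [impute_trajectory()],
#'   or a single observed-only grid (features then computed on observed
#'   cells, used for diagnostics).
#' @param clusters study-level cluster table with `is_home` flagged.
#' @param coverage observed-cell fraction for the day (for bookkeeping).
#' @param coverage_floor minimum observed coverage to emit features when no
#'   imputation is available. Default 0.10.
#' @return one-row data.frame of the eight features plus `coverage` and
#'   `reason`.
#' @export
daily_features <- function(realizations, clusters, coverage = NA_real_,
                           coverage_floor = 0.10) {
  na_row <- data.frame(location_variance = NA_real_, speed_mean = NA_real_,
                       speed_variance = NA_real_, total_distance = NA_real_,
                       transition_time = NA_real_, n_clusters = NA_real_,
                       normalized_entropy = NA_real_, homestay = NA_real_,
                       coverage = coverage, reason = "unimputable",
                       stringsAsFactors = FALSE)
  if (is.null(realizations)) return(na_row)
  if (is.data.frame(realizations)) realizations <- list(realizations)
  per <- lapply(realizations, .features_one, clusters = clusters)
  per <- do.call(rbind, per)
  if (all(is.na(per$location_variance)) &&
      (is.na(coverage) || coverage < coverage_floor)) {
    na_row$reason <- "below_coverage_floor"
    return(na_row)
  }
  out <- as.data.frame(lapply(per, mean, na.rm = TRUE))
  out$coverage <- coverage
  out$reason <- "ok"
  out
}

.features_one <- function(g, clusters) {
  use <- !is.na(g$lat)
  lat <- g$lat[use]; lon <- g$lon[use]
  n <- length(lat)
  if (n < 2L)
    return(data.frame(location_variance = NA_real_, speed_mean = NA_real_,
                      speed_variance = NA_real_, total_distance = NA_real_,
                      transition_time = NA_real_, n_clusters = NA_real_,
                      normalized_entropy = NA_real_, homestay = NA_real_))
  lv <- log(stats::var(lat) + stats::var(lon))
  adj <- which(use[-nrow(g)] & use[-1] & diff(g$cell) == 1L)
  disp <- mercator_distance(g$lat[adj], g$lon[adj],
                            g$lat[adj + 1L], g$lon[adj + 1L])
  moving <- g$state == "moving" & use
  # distance over steps that touch a moving cell: sub-threshold pause jitter
  # is sensor noise, not travel, and would otherwise accumulate over the day
  step_moves <- moving[adj] | moving[adj + 1L]
  total_distance <- sum(disp[step_moves])
  speeds <- disp[moving[adj]] / 10
  speed_mean <- if (length(speeds)) mean(speeds) else 0
  speed_variance <- if (length(speeds) > 1L) stats::var(speeds) else 0
  transition_time <- sum(moving) / n
  # pause time per cluster
  pause <- g$state == "pause" & use
  if (any(pause) && nrow(clusters) > 0L) {
    pd <- data.frame(lat = g$lat[pause], lon = g$lon[pause])
    cl <- assign_clusters(pd, clusters)
    tcl <- vapply(seq_len(nrow(clusters)), function(j) 10 * sum(cl == j), 0)
    visited <- sum(tcl > 0)
    p <- tcl[tcl > 0] / sum(tcl)
    entropy <- -sum(p * log(p))
    nen <- if (visited > 1L) entropy / log(visited) else 0
    home_t <- tcl[which(clusters$is_home)]
    homestay <- if (length(home_t)) home_t / (10 * n) else 0
  } else {
    visited <- 0; nen <- 0; homestay <- 0
  }
  data.frame(location_variance = lv, speed_mean = speed_mean,
             speed_variance = speed_variance, total_distance = total_distance,
             transition_time = transition_time, n_clusters = visited,
             normalized_entropy = nen, homestay = homestay)
}
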