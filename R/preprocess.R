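# GPS cleaning protocol: accuracy filter -> 10-s binning -> motion states ->
# pause aggregation -> simulation-averaged trajectory imputation.

R_EARTH <- 6378137  # WGS84 equatorial radius, meters (spherical Mercator)

MOVE_THRESHOLD_M <- sqrt(10)  # displacement per 10-s step that counts as moving

#' Mercator-projected distance in meters
#'
#' Projects both points to spherical (Web) Mercator and takes the Euclidean
#' distance, corrected by the cosine of the mean latitude so that the result
#' is locally true in meters. Raw Mercator lengths are inflated by
#' 1/cos(latitude) (about 10% at 25 N); the correction removes that while
#' keeping the projection's planar geometry. Vectorized; symmetric; zero iff
#' the points coincide.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 degrees.
#' @return distance(s) in meters.
#' @export
mercator_distance <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  x1 <- R_EARTH * lon1 * d2r
  x2 <- R_EARTH * lon2 * d2r
  y1 <- R_EARTH * log(tan(pi / 4 + lat1 * d2r / 2))
  y2 <- R_EARTH * log(tan(pi / 4 + lat2 * d2r / 2))
  scale <- cos((lat1 + lat2) / 2 * d2r)
  scale * sqrt((x2 - x1)^2 + (y2 - y1)^2)
}

#' Filter GPS fixes by reported accuracy
#'
#' Retains fixes whose accuracy is strictly below the threshold (default 51 m,
#' i.e. accuracy < 51 counts as high accuracy). The retention fraction is
#' attached as attribute `retention`.
#'
#' @param fixes data.frame with an `accuracy` column.
#' @param threshold meters; strict upper bound.
#' @return the retained subset, with attribute `retention`.
#' @export
filter_accuracy <- function(fixes, threshold = 51) {
  stopifnot(!anyNA(fixes$accuracy))
  keep <- fixes$accuracy < threshold
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- if (nrow(fixes)) mean(keep) else NA_real_
  out
}

#' Collapse fixes for one participant-day onto the 10-second grid
#'
#' The day is divided into 8640 half-open cells \[t, t+10) anchored at local
#' midnight. Each occupied cell gets the arithmetic mean latitude/longitude of
#' its fixes (damping GPS-drift speed spikes relative to raw 1 Hz data);
#' unoccupied cells are emitted with state `"missing"`, so the grid always
#' spans the full day.
#'
#' @param sec seconds since local midnight for each fix (see
#'   [seconds_of_day()]).
#' @param lat,lon fix coordinates, degrees.
#' @return data.frame with one row per cell: `cell` (0-8639), `t_start`
#'   (seconds), `lat`, `lon` (NA when missing), `n_fixes`, `state`
#'   (`"observed"` placeholder or `"missing"`), `imputed` (FALSE).
#' @export
bin_10s <- function(sec, lat, lon) {
  stopifnot(length(sec) == length(lat), length(sec) == length(lon))
  ncell <- 8640L
  grid <- data.frame(cell = 0:(ncell - 1L),
                     t_start = 10 * (0:(ncell - 1L)),
                     lat = NA_real_, lon = NA_real_, n_fixes = 0L,
                     state = "missing", imputed = FALSE,
                     stringsAsFactors = FALSE)
  if (length(sec)) {
    idx <- pmin(pmax(floor(sec / 10), 0), ncell - 1L)
    f <- factor(idx, levels = 0:(ncell - 1L))
    n <- tabulate(f, nbins = ncell)
    sum_lat <- vapply(split(lat, f), sum, 0)
    sum_lon <- vapply(split(lon, f), sum, 0)
    occ <- n > 0L
    grid$lat[occ] <- sum_lat[occ] / n[occ]
    grid$lon[occ] <- sum_lon[occ] / n[occ]
    grid$n_fixes <- n
    grid$state[occ] <- "observed"
  }
  grid
}

#' Assign motion states on the 10-second grid
#'
#' For each pair of adjacent (consecutive-cell) observed points the
#' displacement is computed with [mercator_distance()]. A cell whose
#' displacement to an adjacent observed cell exceeds sqrt(10) meters over the
#' 10-s step is `"moving"` ("exceeds" is strict: exactly sqrt(10) is not
#' moving); an observed cell with at least one adjacent observed neighbour and
#' no such displacement is `"pause"`; an observed cell flanked only by missing
#' cells is `"undefined"`; absent cells stay `"missing"`.
#'
#' @param grid data.frame from [bin_10s()].
#' @param move_threshold_m meters per 10-s step; default sqrt(10).
#' @return `grid` with `state` replaced by one of
#'   `"moving"`, `"pause"`, `"undefined"`, `"missing"`.
#' @export
classify_motion <- function(grid, move_threshold_m = MOVE_THRESHOLD_M) {
  obs <- !is.na(grid$lat)
  n <- nrow(grid)
  d_fwd <- rep(NA_real_, n)  # displacement cell i -> cell i+1
  both <- which(obs[-n] & obs[-1])
  if (length(both))
    d_fwd[both] <- mercator_distance(grid$lat[both], grid$lon[both],
                                     grid$lat[both + 1L], grid$lon[both + 1L])
  d_bwd <- c(NA_real_, d_fwd[-n])
  state <- rep("missing", n)
  has_nb <- obs & (!is.na(d_fwd) | !is.na(d_bwd))
  mov <- has_nb & (pmax(d_fwd, d_bwd, na.rm = TRUE) > move_threshold_m)
  state[obs] <- "undefined"
  state[has_nb & !mov] <- "pause"
  state[which(mov)] <- "moving"
  grid$state <- state
  grid
}

#' Aggregate pause cells into pause events
#'
#' Maximal runs of `"pause"` cells become candidate bouts; consecutive bouts
#' are merged into one pause event at the same location when the time between
#' them is at most `pause_window_s` (300 s) and their centroids are strictly
#' within `pause_radius_m` (60 m) of each other, distances by
#' [mercator_distance()]. Event centroids are pause-time-weighted means.
#'
#' @param grid classified day grid from [classify_motion()].
#' @param pause_window_s seconds; merge window. Default 300.
#' @param pause_radius_m meters; merge radius (strict). Default 60.
#' @return data.frame of events: `lat`, `lon` (centroid), `t_begin`, `t_end`
#'   (seconds of day, half-open), `duration` (seconds of pause time).
#' @export
aggregate_pauses <- function(grid, pause_window_s = 300, pause_radius_m = 60) {
  is_p <- grid$state == "pause"
  if (!any(is_p))
    return(data.frame(lat = numeric(0), lon = numeric(0),
                      t_begin = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  r <- rle(is_p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pk <- which(r$values)
  bouts <- data.frame(
    lat = vapply(pk, function(k) mean(grid$lat[starts[k]:ends[k]]), 0),
    lon = vapply(pk, function(k) mean(grid$lon[starts[k]:ends[k]]), 0),
    t_begin = grid$t_start[starts[pk]],
    t_end = grid$t_start[ends[pk]] + 10,
    duration = 10 * r$lengths[pk])
  out <- bouts[1, , drop = FALSE]
  if (nrow(bouts) > 1L) {
    for (j in 2:nrow(bouts)) {
      cur <- nrow(out)
      gap <- bouts$t_begin[j] - out$t_end[cur]
      d <- mercator_distance(out$lat[cur], out$lon[cur],
                             bouts$lat[j], bouts$lon[j])
      if (gap <= pause_window_s && d < pause_radius_m) {
        w1 <- out$duration[cur]; w2 <- bouts$duration[j]
        out$lat[cur] <- (w1 * out$lat[cur] + w2 * bouts$lat[j]) / (w1 + w2)
        out$lon[cur] <- (w1 * out$lon[cur] + w2 * bouts$lon[j]) / (w1 + w2)
        out$t_end[cur] <- bouts$t_end[j]
        out$duration[cur] <- w1 + w2
      } else {
        out <- rbind(out, bouts[j, , drop = FALSE])
      }
    }
  }
  rownames(out) <- NULL
  out
}

# Run RNG code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(master, ...) {
  ks <- c(...)
  s <- master %% 2147483647
  for (k in ks) s <- (s * 48271 + k * 8191 + 1) %% 2147483647
  as.integer(s)
}

#' Impute missing trajectory cells by seeded hot-deck resampling
#'
#' Fills every `"missing"` cell of a classified day grid in each of `n_sim`
#' independent realizations:
#' \itemize{
#'   \item interior gaps whose flanking observed positions agree within
#'     `pause_radius_m` are bridged as a pause at the mean flank position
#'     (for gaps longer than `pause_window_s` the agreement of the flanks,
#'     not the gap length, is the informative signal under duty-cycled
#'     sampling, where every off-window exceeds the window);
#'   \item short gaps (at most `pause_window_s`) with disagreeing flanks are
#'     bridged as a linear flight between the flanks;
#'   \item longer gaps with disagreeing flanks are filled by resampling
#'     observed flight/pause bouts (the donor pool, drawn from the same
#'     day-half, 00:00-12:00 / 12:00-24:00, when available) until the gap
#'     duration is covered, then adding the linear correction that makes the
#'     resampled walk connect the two flanks;
#'   \item gaps touching the day boundary (one flank only) are held as a
#'     pause at the nearest observed position.
#' }
#' Observed cells (including `"undefined"` ones) are never altered;
#' `"undefined"` cells are excluded from the donor pool. States of filled
#' cells are re-derived from their displacements. A day with zero observed
#' cells is unimputable and returns `NULL` with attribute-free messaging left
#' to the caller.
#'
#' @param grid classified day grid from [classify_motion()].
#' @param n_sim number of realizations (the downstream feature average uses
#'   all of them). Default 10.
#' @param seed integer seed; realization r uses a sub-seed derived from it.
#' @param pause_window_s,pause_radius_m,move_threshold_m protocol constants.
#' @return list of `n_sim` complete day grids (no `"missing"` cells), or
#'   `NULL` when the day has no observed cells.
#' @export
impute_trajectory <- function(grid, n_sim = 10, seed = 1,
                              pause_window_s = 300, pause_radius_m = 60,
                              move_threshold_m = MOVE_THRESHOLD_M) {
  obs_idx <- which(!is.na(grid$lat))
  if (length(obs_idx) == 0L) return(NULL)
  n <- nrow(grid)

  # donor pool: observed flight/pause bouts (maximal same-state runs inside
  # contiguous observed stretches); pauses keep only their length, flights
  # keep their 10-s step displacement vectors (degrees)
  pool <- .donor_bouts(grid)

  miss_runs <- .runs_of(is.na(grid$lat))

  fill_one <- function(r_seed) {
    g <- grid
    with_seed(r_seed, {
      for (k in seq_len(nrow(miss_runs))) {
        a <- miss_runs$start[k]; b <- miss_runs$end[k]
        m <- b - a + 1L
        left <- if (a > 1L) a - 1L else NA_integer_
        right <- if (b < n) b + 1L else NA_integer_
        if (is.na(left) && is.na(right)) next  # cannot happen: obs exist
        if (is.na(left) || is.na(right)) {
          anchor <- if (is.na(left)) right else left
          g$lat[a:b] <- grid$lat[anchor]
          g$lon[a:b] <- grid$lon[anchor]
        } else {
          gap_s <- 10 * m
          dflank <- mercator_distance(grid$lat[left], grid$lon[left],
                                      grid$lat[right], grid$lon[right])
          if (dflank < pause_radius_m) {
            g$lat[a:b] <- (grid$lat[left] + grid$lat[right]) / 2
            g$lon[a:b] <- (grid$lon[left] + grid$lon[right]) / 2
          } else if (gap_s <= pause_window_s || is.null(pool)) {
            w <- seq_len(m) / (m + 1)
            g$lat[a:b] <- grid$lat[left] + w * (grid$lat[right] - grid$lat[left])
            g$lon[a:b] <- grid$lon[left] + w * (grid$lon[right] - grid$lon[left])
          } else {
            steps <- .sample_donor_steps(pool, m + 1L,
                                         am = grid$cell[a] < 4320L)
            cum_lat <- cumsum(steps[, 1]); cum_lon <- cumsum(steps[, 2])
            # rescale: shear the walk so its endpoint meets the right flank
            w <- seq_len(m + 1L) / (m + 1L)
            tgt_lat <- grid$lat[right] - grid$lat[left]
            tgt_lon <- grid$lon[right] - grid$lon[left]
            path_lat <- grid$lat[left] + cum_lat + w * (tgt_lat - cum_lat[m + 1L])
            path_lon <- grid$lon[left] + cum_lon + w * (tgt_lon - cum_lon[m + 1L])
            g$lat[a:b] <- path_lat[seq_len(m)]
            g$lon[a:b] <- path_lon[seq_len(m)]
          }
        }
        g$imputed[a:b] <- TRUE
      }
    })
    # re-derive states for imputed cells from displacements
    d_fwd <- c(mercator_distance(g$lat[-n], g$lon[-n], g$lat[-1], g$lon[-1]),
               NA_real_)
    d_bwd <- c(NA_real_, d_fwd[-n])
    mov <- pmax(d_fwd, d_bwd, na.rm = TRUE) > move_threshold_m
    imp <- g$imputed
    g$state[imp] <- ifelse(mov[imp], "moving", "pause")
    g
  }

  lapply(seq_len(n_sim), function(r) fill_one(derive_seed(seed, r)))
}

# Observed flight/pause bouts for hot-deck donation. Each bout is a maximal
# run of one motion state within a contiguous observed stretch: pauses carry
# their length in cells, flights their per-step displacement vectors.
.donor_bouts <- function(grid) {
  n <- nrow(grid)
  usable <- grid$state %in% c("moving", "pause")
  runs <- .runs_of(usable)
  bouts <- list()
  for (k in seq_len(nrow(runs))) {
    ix <- runs$start[k]:runs$end[k]
    st <- grid$state[ix]
    r <- rle(st)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (j in seq_along(r$values)) {
      cells <- ix[s[j]:e[j]]
      am <- grid$cell[cells[1]] < 4320L
      if (r$values[j] == "pause") {
        bouts[[length(bouts) + 1L]] <- list(type = "pause",
                                            len = length(cells), am = am)
      } else {
        from <- cells[-length(cells)]
        if (!length(from)) {
          # single moving cell bounded by run edges: use neighbour step
          nb <- cells[1]
          from <- nb[nb < n & usable[pmin(nb + 1L, n)]]
        }
        if (length(from)) {
          bouts[[length(bouts) + 1L]] <- list(
            type = "flight", len = length(from), am = am,
            dlat = grid$lat[from + 1L] - grid$lat[from],
            dlon = grid$lon[from + 1L] - grid$lon[from])
        }
      }
    }
  }
  if (!length(bouts)) return(NULL)
  bouts
}

# Concatenate sampled donor bouts into n_steps 10-s displacement vectors,
# preferring bouts from the same day half.
.sample_donor_steps <- function(pool, n_steps, am) {
  match_half <- vapply(pool, function(b) b$am == am, TRUE)
  cand <- if (any(match_half)) pool[match_half] else pool
  out <- matrix(0, n_steps, 2)
  filled <- 0L
  while (filled < n_steps) {
    b <- cand[[sample.int(length(cand), 1L)]]
    take <- min(b$len, n_steps - filled)
    if (b$type == "flight")
      out[filled + seq_len(take), ] <- cbind(b$dlat[seq_len(take)],
                                             b$dlon[seq_len(take)])
    filled <- filled + take
  }
  out
}

.runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}
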