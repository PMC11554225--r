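#' Read a moon-illumination table
#'
#' CSV with columns `date` (ISO dates) and `percent_illuminated` in
#' `[0, 100]`: the fraction of the lunar disk illuminated on that date
#' (location-independent, taken at 00:00 UTC).
#'
#' @param path CSV path.
#' @return Data frame with `date` (class `Date`) and `percent_illuminated`.
#' @export
read_moon_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "percent_illuminated") %in% names(d)))
    stop("moon table needs columns date, percent_illuminated")
  out <- data.frame(date = as.Date(d$date),
                    percent_illuminated = as.numeric(d$percent_illuminated))
  if (any(is.na(out$date)) ||
      any(out$percent_illuminated < 0 | out$percent_illuminated > 100))
    stop("invalid moon table values")
  out
}

#' Moon illumination for dates
#' @param dates `Date` vector.
#' @param moon Table from [read_moon_table()].
#' @return Percent illumination per date (`NA` when absent from the table).
#' @export
moon_at <- function(dates, moon) {
  moon$percent_illuminated[match(as.Date(dates), moon$date)]
}

#' Sample bathymetry depth at ping locations
#'
#' Nearest-cell (containing-cell) sampling from a bathymetry raster in
#' lon/lat. Depths are positive metres below datum; rasters stored
#' negative-down can be negated on read with `negate_down = TRUE`.
#'
#' @param pings Ping data frame with `lon`, `lat`.
#' @param bathy A `"value_grid"` in degrees (`proj = NULL`).
#' @param negate_down Negate raster values (for negative-down conventions).
#' @return Numeric depth per ping, metres; `NA` (flagged) for pings outside
#'   the raster extent or in no-data cells.
#' @export
depth_at <- function(pings, bathy, negate_down = FALSE) {
  stopifnot(inherits(bathy, "value_grid"))
  ci <- cell_index(bathy$spec, pings$lon, pings$lat)
  d <- rep(NA_real_, nrow(pings))
  ok <- ci$inside
  d[ok] <- bathy$values[cbind(ci$row[ok], ci$col[ok])]
  if (negate_down) d <- -d
  d
}

# Rolling sum over a centered window of +/- half steps, truncated at the
# ends; returns list(sum, n). O(n) via cumulative sums.
roll_sum <- function(x, half) {
  n <- length(x)
  i <- seq_len(n)
  a <- pmax(1L, i - half)
  b <- pmin(n, i + half)
  cs <- c(0, cumsum(x))
  list(sum = cs[b + 1] - cs[a], n = b - a + 1, a = a, b = b)
}

#' Rolling-window trajectory features
#'
#' Computes, for every ping of a 1-minute resampled track, summary features
#' over a centered 15-minute window (at most 7 minutes either side, clipped
#' to segment bounds):
#' \describe{
#'   \item{sog_avg, sog_std}{mean / SD of speed over ground, knots}
#'   \item{crow_flies_km}{geodesic distance from the window's first to last
#'     position}
#'   \item{total_dist_km}{sum of consecutive geodesic step distances within
#'     the window}
#'   \item{depth_avg, depth_std}{mean / SD of sampled depth, metres}
#'   \item{cog_avg_abs_d}{mean absolute consecutive course change, degrees}
#'   \item{d_cog_startend}{signed minimal course change from window start to
#'     end, degrees in (-180, 180]}
#'   \item{moon}{percent lunar illumination for the ping's date}
#'   \item{month, day_of_week}{calendar integer codes (day 0 = Sunday),
#'     computed in `tz`}
#' }
#' Windows holding fewer than `min_pings` pings, or any ping lacking a depth
#' when bathymetry is supplied, are flagged `valid = FALSE`.
#'
#' @param pings Resampled pings (see [resample_tracks()]) with a `segment`
#'   column.
#' @param window_min Window length in minutes (default 15; centered).
#' @param min_pings Minimum window occupancy (default 5).
#' @param bathy Optional bathymetry `"value_grid"`; omitted, depth features
#'   are `NA`.
#' @param moon Optional moon table (see [read_moon_table()]).
#' @param tz Timezone for calendar features (default `"UTC"`).
#' @param negate_down Passed to [depth_at()].
#' @return `pings` with feature columns, `n_window` and `valid` appended.
#' @export
window_features <- function(pings, window_min = 15, min_pings = 5,
                            bathy = NULL, moon = NULL, tz = "UTC",
                            negate_down = FALSE) {
  half <- floor(window_min / 2)
  depth <- if (!is.null(bathy)) depth_at(pings, bathy, negate_down)
           else rep(NA_real_, nrow(pings))
  key <- paste(pings$trip_id, pings$segment, sep = "\r")
  idx_parts <- split(seq_len(nrow(pings)), key)
  feats <- matrix(NA_real_, nrow(pings), 11,
                  dimnames = list(NULL, c(
                    "sog_avg", "sog_std", "crow_flies_km", "total_dist_km",
                    "depth_avg", "depth_std", "cog_avg_abs_d",
                    "d_cog_startend", "moon", "month", "day_of_week")))
  n_window <- integer(nrow(pings))
  for (idx in idx_parts) {
    n <- length(idx)
    sog <- pings$sog[idx]
    lat <- pings$lat[idx]
    lon <- pings$lon[idx]
    cog <- pings$cog[idx]
    dep <- depth[idx]
    rs <- roll_sum(sog, half)
    n_window[idx] <- rs$n
    feats[idx, "sog_avg"] <- rs$sum / rs$n
    rq <- roll_sum(sog^2, half)
    feats[idx, "sog_std"] <- trunc_sd(rq$sum, rs$sum, rs$n)
    feats[idx, "crow_flies_km"] <-
      geodesic_km(lat[rs$a], lon[rs$a], lat[rs$b], lon[rs$b])
    if (n >= 2) {
      step <- geodesic_km(lat[-n], lon[-n], lat[-1], lon[-1])
      # window a..b covers steps a..b-1
      css <- c(0, cumsum(step))
      feats[idx, "total_dist_km"] <- css[rs$b] - css[rs$a]
      turn <- abs(heading_change(cog[-n], cog[-1]))
      cst <- c(0, cumsum(turn))
      nstep <- rs$b - rs$a
      feats[idx, "cog_avg_abs_d"] <-
        ifelse(nstep > 0, (cst[rs$b] - cst[rs$a]) / nstep, 0)
    } else {
      feats[idx, "total_dist_km"] <- 0
      feats[idx, "cog_avg_abs_d"] <- 0
    }
    feats[idx, "d_cog_startend"] <- heading_change(cog[rs$a], cog[rs$b])
    rd <- roll_sum(ifelse(is.na(dep), 0, dep), half)
    rdq <- roll_sum(ifelse(is.na(dep), 0, dep)^2, half)
    if (!anyNA(dep)) {
      feats[idx, "depth_avg"] <- rd$sum / rd$n
      feats[idx, "depth_std"] <- trunc_sd(rdq$sum, rd$sum, rd$n)
    } else if (!all(is.na(dep))) {
      # windows touching a no-data ping stay NA and are invalidated below
      okd <- !is.na(dep)
      rn <- roll_sum(as.numeric(okd), half)
      full <- rn$sum == rn$n
      feats[idx[full], "depth_avg"] <- (rd$sum / rd$n)[full]
      feats[idx[full], "depth_std"] <- trunc_sd(rdq$sum, rd$sum, rd$n)[full]
    }
  }
  lt <- as.POSIXlt(pings$timestamp, tz = tz)
  feats[, "month"] <- lt$mon + 1
  feats[, "day_of_week"] <- lt$wday
  if (!is.null(moon)) feats[, "moon"] <- moon_at(as.Date(lt), moon)
  out <- cbind(pings, as.data.frame(feats), n_window = n_window)
  out$valid <- out$n_window >= min_pings &
    (is.null(bathy) | !is.na(out$depth_avg))
  out
}

# SD from rolling sum and sum of squares, sample convention. Variances
# below the cancellation noise floor of the two-pass formula are clamped
# to exact zero so constant windows report sd 0.
trunc_sd <- function(sumsq, s, n) {
  v <- (sumsq - s^2 / n) / pmax(n - 1, 1)
  v[n < 2] <- 0
  v[v < 1e-10 * (sumsq / n + 1)] <- 0
  sqrt(pmax(v, 0))
}

#' Label pings as fishing from observer hauls
#'
#' A ping is fishing iff its timestamp lies in the *closed* interval
#' `[start, end]` of any haul of its trip. Pings of trips without observer
#' coverage get `NA` labels. (Window-based labeling — marking a ping
#' fishing when gear was deployed anywhere in its surrounding window — is a
#' possible extension point; only timestamp-interval labeling is
#' implemented.)
#'
#' @param pings Ping or feature data frame with `trip_id`, `timestamp`.
#' @param hauls Haul data frame (see [read_hauls()]).
#' @param trips Optional trip data frame; when given, hauls referencing
#'   unknown trips are a fatal error.
#' @return `pings` with a logical `fishing` column.
#' @export
label_fishing <- function(pings, hauls, trips = NULL) {
  if (!is.null(trips)) {
    unknown <- setdiff(hauls$trip_id, trips$trip_id)
    if (length(unknown))
      stop("hauls reference unknown trip(s): ",
           paste(unknown, collapse = ", "))
  }
  pings$fishing <- NA
  covered <- pings$trip_id %in% hauls$trip_id
  pings$fishing[covered] <- FALSE
  for (tid in intersect(unique(pings$trip_id), unique(hauls$trip_id))) {
    sel <- which(pings$trip_id == tid)
    tt <- as.numeric(pings$timestamp[sel])
    h <- hauls[hauls$trip_id == tid, , drop = FALSE]
    fish <- rep(FALSE, length(sel))
    for (j in seq_len(nrow(h))) {
      fish <- fish | (tt >= as.numeric(h$start[j]) &
                        tt <= as.numeric(h$end[j]))
    }
    pings$fishing[sel] <- fish
  }
  pings
}
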