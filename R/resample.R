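#' Resample one trip's pings onto a regular time grid
#'
#' Produces pings on an exact `interval`-second grid from the first to the
#' last observed timestamp, linearly interpolating `lat`, `lon` and `sog` in
#' time. Course over ground is unwrapped to a continuous angle before linear
#' interpolation and rewrapped to `[0, 360)`, so interpolation never crosses
#' the 0/360 seam the long way. Gaps longer than `max_gap` seconds are not
#' interpolated: the track is split into segments and the grid restarts at
#' each segment's first observed ping. Observed timestamps that fall on the
#' grid keep their observed values; inserted pings are marked
#' `interpolated = TRUE`.
#'
#' @param pings Pings of a single trip (strictly increasing timestamps).
#' @param interval Grid spacing in seconds (default 60).
#' @param max_gap Maximum gap to interpolate across, seconds (default 1800).
#' @return Resampled ping data frame with an added `segment` column; a
#'   single-ping input is returned unchanged (with `segment = 1`) and
#'   attribute `"single_ping" = TRUE`.
#' @export
resample_trip <- function(pings, interval = 60, max_gap = 1800) {
  stopifnot(nrow(pings) >= 1)
  keep <- c("vessel_id", "trip_id", "timestamp", "lat", "lon", "sog",
            "cog", "source", "interpolated")
  pings <- pings[, intersect(keep, names(pings)), drop = FALSE]
  tt <- as.numeric(pings$timestamp)
  if (is.unsorted(tt, strictly = TRUE))
    stop("timestamps must be strictly increasing within a trip")
  if (nrow(pings) == 1) {
    pings$segment <- 1L
    attr(pings, "single_ping") <- TRUE
    warning("single-ping trip returned unchanged")
    return(pings)
  }
  seg <- cumsum(c(1L, as.integer(diff(tt) > max_gap)))
  out <- lapply(split(seq_along(tt), seg), function(idx) {
    p <- pings[idx, , drop = FALSE]
    if (nrow(p) == 1) {
      p$segment <- NA_integer_
      return(p)
    }
    t0 <- as.numeric(p$timestamp[1])
    t1 <- as.numeric(p$timestamp[nrow(p)])
    grid <- seq(t0, t1, by = interval)
    ot <- as.numeric(p$timestamp)
    lat <- stats::approx(ot, p$lat, grid)$y
    lon <- stats::approx(ot, p$lon, grid)$y
    sog <- stats::approx(ot, p$sog, grid)$y
    cogu <- stats::approx(ot, unwrap_heading(p$cog), grid)$y
    obs <- match(grid, ot)
    hit <- !is.na(obs)
    # observed grid points keep observed values exactly
    lat[hit] <- p$lat[obs[hit]]
    lon[hit] <- p$lon[obs[hit]]
    sog[hit] <- p$sog[obs[hit]]
    cogu[hit] <- p$cog[obs[hit]]
    data.frame(
      vessel_id = p$vessel_id[1], trip_id = p$trip_id[1],
      timestamp = as.POSIXct(grid, tz = "UTC", origin = "1970-01-01"),
      lat = lat, lon = lon, sog = sog, cog = cogu %% 360,
      source = p$source[1], interpolated = !hit,
      segment = NA_integer_, stringsAsFactors = FALSE
    )
  })
  for (i in seq_along(out)) out[[i]]$segment <- i
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resample all trips in a ping set
#'
#' Applies [resample_trip()] per `trip_id`; pings without a trip are dropped.
#'
#' @inheritParams resample_trip
#' @param pings Ping data frame with `trip_id` set (see [link_trips()]).
#' @return Resampled pings for all trips, with `segment` column.
#' @export
resample_tracks <- function(pings, interval = 60, max_gap = 1800) {
  pings <- pings[!is.na(pings$trip_id), , drop = FALSE]
  parts <- split(pings, pings$trip_id)
  out <- lapply(parts, resample_trip, interval = interval, max_gap = max_gap)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
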