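#' Read vessel position tracks from CSV
#'
#' Expects a headered CSV with columns `vessel_id, timestamp, lat, lon, sog,
#' cog` (ISO-8601 UTC timestamps). The public AIS archive dialect
#' (`MMSI, BaseDateTime, LAT, LON, SOG, COG`) or any other naming is handled
#' via `col_map`. Rows violating ping invariants are dropped and counted in
#' the attached `"report"` attribute; duplicate `(vessel, timestamp)` rows
#' keep the first occurrence.
#'
#' @param path CSV path.
#' @param source `"AIS"` or `"VMS"`; stored in the `source` column.
#' @param col_map Optional named character vector mapping canonical names to
#'   file column names, e.g. `c(vessel_id = "MMSI", timestamp =
#'   "BaseDateTime", lat = "LAT", lon = "LON", sog = "SOG", cog = "COG")`.
#' @return A data frame of validated pings sorted by `(vessel_id,
#'   timestamp)`, with columns `vessel_id, trip_id, timestamp, lat, lon, sog,
#'   cog, source, interpolated` and attribute `"report"` (a list with counts
#'   of read, kept, rejected and duplicate rows).
#' @export
read_tracks <- function(path, source = c("AIS", "VMS"), col_map = NULL) {
  source <- match.arg(source)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("vessel_id", "timestamp", "lat", "lon", "sog", "cog")
  if (!is.null(col_map)) {
    missing_map <- setdiff(need, names(col_map))
    if (length(missing_map))
      stop("col_map must map all of: ", paste(need, collapse = ", "))
    if (!all(col_map %in% names(raw)))
      stop("missing required column(s): ",
           paste(setdiff(col_map, names(raw)), collapse = ", "))
    raw <- raw[, unname(col_map[need])]
    names(raw) <- need
  } else {
    if (!all(need %in% names(raw)))
      stop("missing required column(s): ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    raw <- raw[, need]
  }
  n_in <- nrow(raw)
  ts <- parse_utc(raw$timestamp)
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  sog <- suppressWarnings(as.numeric(raw$sog))
  cog <- suppressWarnings(as.numeric(raw$cog))
  bad_ts <- is.na(ts)
  bad_coord <- is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
    lon < -180 | lon > 180
  bad_kin <- is.na(sog) | sog < 0 | is.na(cog) | cog < 0 | cog >= 360
  keep <- !(bad_ts | bad_coord | bad_kin)
  pings <- data.frame(
    vessel_id = raw$vessel_id[keep], trip_id = NA_character_,
    timestamp = ts[keep], lat = lat[keep], lon = lon[keep],
    sog = sog[keep], cog = cog[keep], source = source,
    interpolated = FALSE, stringsAsFactors = FALSE
  )
  pings <- pings[order(pings$vessel_id, pings$timestamp), , drop = FALSE]
  dup <- duplicated(pings[, c("vessel_id", "timestamp")])
  n_dup <- sum(dup)
  pings <- pings[!dup, , drop = FALSE]
  rownames(pings) <- NULL
  attr(pings, "report") <- list(
    n_read = n_in, n_kept = nrow(pings),
    n_rejected = sum(!keep), n_duplicates = n_dup,
    rejected = c(timestamp = sum(bad_ts),
                 coordinates = sum(bad_coord & !bad_ts),
                 kinematics = sum(bad_kin & !bad_ts & !bad_coord))
  )
  pings
}

parse_utc <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read trip records from CSV
#'
#' Columns: `trip_id, vessel_id, depart, return, landed_value` (UTC
#' timestamps; ex-vessel dollars).
#' @param path CSV path.
#' @return Data frame with parsed timestamps.
#' @export
read_trips <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("trip_id", "vessel_id", "depart", "return", "landed_value")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  out <- data.frame(
    trip_id = d$trip_id, vessel_id = d$vessel_id,
    depart = parse_utc(d$depart), return = parse_utc(d$return),
    landed_value = as.numeric(d$landed_value), stringsAsFactors = FALSE
  )
  bad <- is.na(out$depart) | is.na(out$return) | out$depart >= out$return |
    !is.finite(out$landed_value) | out$landed_value < 0
  if (any(bad))
    stop("invalid trip rows: ", paste(out$trip_id[bad], collapse = ", "))
  out
}

#' Read observer haul records from CSV
#'
#' Columns: `trip_id, start, end, start_lat, start_lon, end_lat, end_lon`.
#' @param path CSV path.
#' @return Data frame with parsed timestamps.
#' @export
read_hauls <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("trip_id", "start", "end", "start_lat", "start_lon",
            "end_lat", "end_lon")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  out <- data.frame(
    trip_id = d$trip_id, start = parse_utc(d$start), end = parse_utc(d$end),
    start_lat = as.numeric(d$start_lat), start_lon = as.numeric(d$start_lon),
    end_lat = as.numeric(d$end_lat), end_lon = as.numeric(d$end_lon),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("haul with start >= end")
  out
}

#' Read vessel trip reports (single reported location per trip)
#'
#' Columns: `trip_id, reported_lat, reported_lon, landed_value`.
#' @param path CSV path.
#' @return Data frame; one row per trip.
#' @export
read_vtr_reports <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trip_id", "reported_lat", "reported_lon", "landed_value")
  if (!all(need %in% names(d)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (anyDuplicated(d$trip_id)) stop("multiple VTR reports for one trip")
  d[, need]
}

#' Assign pings to trips by vessel and temporal containment
#'
#' A ping whose timestamp falls within `[depart, return]` of a trip for its
#' vessel receives that `trip_id`; other pings keep `NA`. Trips of one
#' vessel must not overlap.
#'
#' @param pings Ping data frame (see [read_tracks()]).
#' @param trips Trip data frame (see [read_trips()]).
#' @return `pings` with `trip_id` filled in.
#' @export
link_trips <- function(pings, trips) {
  for (v in unique(trips$vessel_id)) {
    tv <- trips[trips$vessel_id == v, , drop = FALSE]
    tv <- tv[order(tv$depart), , drop = FALSE]
    if (nrow(tv) > 1) {
      ov <- which(tv$depart[-1] < tv$return[-nrow(tv)])
      if (length(ov))
        stop("overlapping trips for vessel ", v, ": ",
             paste(unique(c(tv$trip_id[ov], tv$trip_id[ov + 1])),
                   collapse = ", "))
    }
  }
  pings$trip_id <- NA_character_
  for (v in unique(pings$vessel_id)) {
    tv <- trips[trips$vessel_id == v, , drop = FALSE]
    if (!nrow(tv)) next
    tv <- tv[order(tv$depart), , drop = FALSE]
    sel <- which(pings$vessel_id == v)
    tt <- as.numeric(pings$timestamp[sel])
    idx <- findInterval(tt, as.numeric(tv$depart))
    hit <- idx >= 1 & tt <= as.numeric(tv$return)[pmax(idx, 1)]
    pings$trip_id[sel[hit]] <- tv$trip_id[idx[hit]]
  }
  pings
}

#' Remove pings inside exclusion polygons
#'
#' Drops pings *strictly inside* any polygon (e.g. state waters); pings on a
#' polygon boundary are retained. Invalid geometries (unclosed rings) are a
#' fatal error at polygon construction.
#'
#' @param pings Ping data frame.
#' @param polygons A `"polygon_set"` in lon/lat (see [read_polygons()]), or
#'   anything [as_polygon_set()] accepts; an empty set is a no-op.
#' @return Filtered ping data frame; number removed in attribute
#'   `"n_removed"`.
#' @export
mask_exclusion_zone <- function(pings, polygons) {
  if (is.null(polygons) || length(polygons) == 0) {
    attr(pings, "n_removed") <- 0L
    return(pings)
  }
  polygons <- as_polygon_set(polygons)
  loc <- points_in_polygon(pings$lon, pings$lat, polygons, eps = 1e-9)
  out <- pings[loc != 1L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- attr(pings, "report")
  attr(out, "n_removed") <- sum(loc == 1L)
  out
}
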