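track_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_tracks keeps valid rows and drops invariant violations", {
  d <- data.frame(
    vessel_id = "V1",
    timestamp = c("2016-05-01T10:00:00Z", "2016-05-01T10:01:00Z",
                  "2016-05-01T10:02:00Z"),
    lat = c(40.1, 40.2, 40.3), lon = c(-70.1, -70.2, -70.3),
    sog = c(4, 5, 6), cog = c(10, 20, 30))
  p <- read_tracks(track_csv(d), "AIS")
  expect_equal(nrow(p), 3)
  expect_equal(attr(p, "report")$n_rejected, 0)
  expect_s3_class(p$timestamp, "POSIXct")

  d2 <- d
  d2$lat[2] <- 95
  p2 <- read_tracks(track_csv(d2), "AIS")
  expect_equal(nrow(p2), 2)
  expect_equal(attr(p2, "report")$n_rejected, 1)

  d3 <- d
  d3$timestamp[1] <- "not-a-time"
  p3 <- read_tracks(track_csv(d3), "AIS")
  expect_equal(nrow(p3), 2)

  expect_error(read_tracks(track_csv(d[, -3]), "AIS"), "missing required")
})

test_that("duplicate (vessel, timestamp) rows collapse to first occurrence", {
  set.seed(11)
  n <- 1000
  base <- data.frame(
    vessel_id = sprintf("V%d", sample.int(4, n, replace = TRUE)),
    timestamp = format(
      as.POSIXct("2016-01-01", tz = "UTC") + sample.int(5e5, n),
      "%Y-%m-%dT%H:%M:%SZ"),
    lat = runif(n, 40, 41), lon = runif(n, -71, -70),
    sog = runif(n, 0, 12), cog = runif(n, 0, 359.9))
  dup_rows <- base[sample.int(n, 5), ]
  dup_rows$lat <- dup_rows$lat + 0.5  # different payload, same key
  mixed <- rbind(base, dup_rows)[sample.int(n + 5), ]
  p <- read_tracks(track_csv(mixed), "AIS")
  # oracle: linear scan with a seen-set over the sorted rows
  srt <- mixed[order(mixed$vessel_id, mixed$timestamp), ]
  seen <- character(0)
  n_dup <- 0L
  for (i in seq_len(nrow(srt))) {
    key <- paste(srt$vessel_id[i], srt$timestamp[i])
    if (key %in% seen) n_dup <- n_dup + 1L else seen <- c(seen, key)
  }
  expect_equal(attr(p, "report")$n_duplicates, n_dup)
  expect_equal(nrow(p), length(seen))
  expect_false(any(duplicated(p[, c("vessel_id", "timestamp")])))
})

test_that("read_tracks maps the public AIS archive dialect", {
  d <- data.frame(MMSI = "368000123", BaseDateTime = "2016-05-01T10:00:00",
                  LAT = 40.1, LON = -70.1, SOG = 4.2, COG = 112.5)
  p <- read_tracks(track_csv(d), "AIS",
                   col_map = c(vessel_id = "MMSI",
                               timestamp = "BaseDateTime", lat = "LAT",
                               lon = "LON", sog = "SOG", cog = "COG"))
  expect_equal(p$vessel_id, "368000123")
  expect_equal(p$cog, 112.5)
})

test_that("link_trips assigns by temporal containment with closed bounds", {
  trips <- data.frame(
    trip_id = c("T1", "T2"), vessel_id = "V1",
    depart = as.POSIXct(c("2016-05-01 06:00", "2016-05-03 06:00"),
                        tz = "UTC"),
    return = as.POSIXct(c("2016-05-01 18:00", "2016-05-03 18:00"),
                        tz = "UTC"),
    landed_value = c(1000, 2000))
  mk <- function(ts) data.frame(vessel_id = "V1", trip_id = NA,
                                timestamp = as.POSIXct(ts, tz = "UTC"),
                                lat = 40.5, lon = -70.5, sog = 5, cog = 0,
                                source = "AIS", interpolated = FALSE)
  expect_equal(link_trips(mk("2016-05-01 12:00"), trips)$trip_id, "T1")
  expect_true(is.na(link_trips(mk("2016-05-01 18:00:01"), trips)$trip_id))
  expect_equal(link_trips(mk("2016-05-01 18:00:00"), trips)$trip_id, "T1")
})

test_that("link_trips equals a brute-force interval test on random data", {
  set.seed(21)
  n_tr <- 10
  dep <- sort(as.POSIXct("2016-01-01", tz = "UTC") +
                sample.int(2e6, n_tr) * 10)
  trips <- data.frame(
    trip_id = sprintf("T%02d", 1:n_tr), vessel_id = "V9",
    depart = dep, return = dep + runif(n_tr, 3600, 40000),
    landed_value = 0)
  # guarantee non-overlap
  for (i in 2:n_tr) {
    trips$return[i - 1] <- min(trips$return[i - 1],
                               trips$depart[i] - 1)
  }
  pings <- data.frame(
    vessel_id = "V9", trip_id = NA,
    timestamp = as.POSIXct("2016-01-01", tz = "UTC") +
      sort(sample.int(2.2e7, 500)),
    lat = 40, lon = -70, sog = 5, cog = 0, source = "AIS",
    interpolated = FALSE)
  got <- link_trips(pings, trips)$trip_id
  want <- vapply(seq_len(500), function(i) {
    hit <- which(pings$timestamp[i] >= trips$depart &
                   pings$timestamp[i] <= trips$return)
    if (length(hit)) trips$trip_id[hit] else NA_character_
  }, "")
  expect_identical(got, want)
})

test_that("overlapping trips for one vessel are fatal", {
  trips <- data.frame(
    trip_id = c("A", "B"), vessel_id = "V1",
    depart = as.POSIXct(c("2016-05-01 06:00", "2016-05-01 12:00"),
                        tz = "UTC"),
    return = as.POSIXct(c("2016-05-01 18:00", "2016-05-02 00:00"),
                        tz = "UTC"),
    landed_value = 0)
  pings <- data.frame(vessel_id = "V1", trip_id = NA,
                      timestamp = as.POSIXct("2016-05-01 13:00", tz = "UTC"),
                      lat = 40, lon = -70, sog = 1, cog = 1,
                      source = "AIS", interpolated = FALSE)
  expect_error(link_trips(pings, trips), "overlapping trips.*V1")
})

test_that("exclusion masking removes strictly-inside points only", {
  sq <- cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0))
  mk <- function(lon, lat) data.frame(vessel_id = "V", trip_id = NA,
                                      timestamp = Sys.time(), lat = lat,
                                      lon = lon, sog = 1, cog = 1,
                                      source = "AIS", interpolated = FALSE)
  pts <- mk(c(0.5, 0.5, 2, 1), c(0.5, 0, 2, 0.5))  # inside, edge, out, edge
  out <- mask_exclusion_zone(pts, list(list(sq)))
  expect_equal(nrow(out), 3)           # boundary points retained
  expect_equal(attr(out, "n_removed"), 1)
  expect_equal(nrow(mask_exclusion_zone(pts, NULL)), 4)
  expect_equal(nrow(mask_exclusion_zone(pts, list())), 4)
})

test_that("point-in-polygon agrees with ray casting and mgcv on random points", {
  set.seed(5)
  ring <- cbind(lon = c(0.1, 0.9, 0.7, 0.5, 0.1, 0.1),
                lat = c(0.1, 0.2, 0.9, 0.5, 0.8, 0.1))  # concave
  px <- runif(400)
  py <- runif(400)
  got <- points_in_polygon(px, py, list(list(ring))) == 1L
  want <- ray_cast_inside(px, py, ring)
  expect_equal(got, want)
  if (requireNamespace("mgcv", quietly = TRUE)) {
    expect_equal(got, mgcv::in.out(ring, cbind(px, py)))
  }
})

test_that("resampling is the identity on exact 1-minute grids", {
  t0 <- as.POSIXct("2016-05-01 10:00:00", tz = "UTC")
  p <- data.frame(vessel_id = "V", trip_id = "T",
                  timestamp = t0 + 60 * (0:9),
                  lat = 40 + (0:9) / 100, lon = -70 - (0:9) / 100,
                  sog = 5 + (0:9) / 10, cog = (0:9) * 5,
                  source = "AIS", interpolated = FALSE)
  r <- resample_trip(p)
  expect_equal(nrow(r), 10)
  expect_equal(r$lat, p$lat)
  expect_equal(r$sog, p$sog)
  expect_equal(r$cog, p$cog)
  expect_false(any(r$interpolated))
  # idempotence
  r2 <- resample_trip(r)
  expect_equal(r2[, c("lat", "lon", "sog", "cog")],
               r[, c("lat", "lon", "sog", "cog")])
})

test_that("interpolation is linear in time and circular in course", {
  t0 <- as.POSIXct("2016-05-01 10:00:00", tz = "UTC")
  p <- data.frame(vessel_id = "V", trip_id = "T",
                  timestamp = t0 + c(0, 120),
                  lat = c(40, 40.2), lon = c(-70, -70.2),
                  sog = c(4, 6), cog = c(350, 10),
                  source = "AIS", interpolated = FALSE)
  r <- resample_trip(p)
  expect_equal(nrow(r), 3)
  expect_equal(r$sog[2], 5)
  expect_equal(r$cog[2], 0)            # across the seam, not 180
  expect_true(r$interpolated[2])
})

test_that("resampled output matches the closed-form interpolation oracle", {
  set.seed(31)
  t0 <- as.POSIXct("2016-05-01 10:00:00", tz = "UTC")
  offs <- sort(c(0, sample(seq(15, 1785, 15), 8), 1800))
  p <- data.frame(vessel_id = "V", trip_id = "T", timestamp = t0 + offs,
                  lat = 40 + cumsum(runif(10, 0, 0.01)),
                  lon = -70 - cumsum(runif(10, 0, 0.01)),
                  sog = runif(10, 3, 9), cog = runif(10, 0, 359),
                  source = "AIS", interpolated = FALSE)
  r <- resample_trip(p)
  expect_equal(nrow(r), 31)
  expect_equal(as.numeric(diff(r$timestamp), units = "secs"),
               rep(60, 30))
  # oracle: evaluate the per-field linear interpolant directly
  interp <- function(v, tg) {
    i <- findInterval(tg, offs, rightmost.closed = TRUE)
    i <- pmin(i, length(offs) - 1)
    w <- (tg - offs[i]) / (offs[i + 1] - offs[i])
    v[i] * (1 - w) + v[i + 1] * w
  }
  tg <- 60 * (0:30)
  expect_equal(r$lat, interp(p$lat, tg), tolerance = 1e-12)
  expect_equal(r$sog, interp(p$sog, tg), tolerance = 1e-12)
  uw <- p$cog[1] + c(0, cumsum(heading_change(p$cog[-10], p$cog[-1])))
  expect_equal(r$cog, interp(uw, tg) %% 360, tolerance = 1e-12)
  # observed timestamps that fall on the grid keep observed values
  on_grid <- offs %% 60 == 0
  at_obs <- match(offs[on_grid], tg)
  expect_equal(r$lat[at_obs], p$lat[on_grid])
  expect_false(any(r$interpolated[at_obs]))
  # no overshoot for linearly interpolated fields
  expect_true(all(r$sog >= min(p$sog) - 1e-12 &
                    r$sog <= max(p$sog) + 1e-12))
})

test_that("gaps beyond max_gap split segments instead of interpolating", {
  t0 <- as.POSIXct("2016-05-01 10:00:00", tz = "UTC")
  p <- data.frame(vessel_id = "V", trip_id = "T",
                  timestamp = t0 + c(0, 60, 7200, 7260),
                  lat = c(40, 40.01, 41, 41.01),
                  lon = -70, sog = 5, cog = 0,
                  source = "AIS", interpolated = FALSE)
  r <- resample_trip(p, max_gap = 1800)
  expect_equal(unique(r$segment), c(1L, 2L))
  expect_equal(nrow(r), 4)             # nothing invented across the gap
  expect_warning(resample_trip(p[1, ]), "single-ping")
})
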