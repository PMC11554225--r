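#' Configuration of the synthetic scallop fleet
#'
#' Parameters of the two-state (transit / dredging) vessel-behavior model
#' and of the degraded observation products derived from it. Defaults
#' describe a Southern New England dredge fleet: transit near 9 knots,
#' dredging near 4.5 knots with speed distributions crossing the 5-knot
#' rule-of-thumb, tight turning while towing, hour-scale dredging bouts,
#' sparse observer coverage, hourly VMS polls and a single shoreline-biased
#' VTR point per trip.
#'
#' @param n_vessels Number of vessels.
#' @param trips_per_vessel Trips per vessel (one per sampled day).
#' @param transit_speed,fishing_speed `c(mean, sd)` of speed over ground by
#'   state, knots.
#' @param speed_ar Lag-1 autocorrelation of the within-state speed process
#'   (AR(1) with the stated stationary mean/SD).
#' @param transit_turn_sd,fishing_turn_sd Per-minute heading noise SD,
#'   degrees.
#' @param fishing_dwell,transit_dwell Mean state dwell times, minutes
#'   (exponential).
#' @param end_leg Outbound/inbound steaming budget at the trip ends, minutes.
#' @param trip_hours `c(min, max)` trip duration, hours (uniform).
#' @param observer_coverage Fraction of AIS trips carrying an observer.
#' @param vms_interval VMS poll interval, minutes.
#' @param vtr_rule Reported-location rule: `"first_haul"`, `"last_haul"` or
#'   `"max_catch"`.
#' @param footprint_sd_km Gaussian footprint kernel SD, km.
#' @param haul_value_mean,haul_value_sd Per-haul ex-vessel value, USD
#'   (normal, truncated at $200).
#' @param p_ais Probability a vessel carries AIS.
#' @param p_vms_no_ais,p_vms_ais VMS carriage probability for vessels
#'   without / with AIS.
#' @param ais_dropout Per-ping AIS dropout probability.
#' @param lon_range,lat_range Study-area extent, degrees.
#' @param port `c(lon, lat)` of the home port.
#' @param state_waters_lat Latitude south of which waters are federal; the
#'   strip north of it is the exclusion (state-waters) polygon.
#' @param n_grounds,ground_sd_km Number and spatial scale of fishing
#'   grounds.
#' @param n_leases,lease_km Number and edge length (km) of square lease
#'   polygons, placed over the first grounds.
#' @param years Calendar years trips are drawn from.
#' @return A list of class `"fleet_config"`.
#' @export
fleet_config <- function(n_vessels = 20, trips_per_vessel = 8,
                         transit_speed = c(mean = 9, sd = 1),
                         fishing_speed = c(mean = 4.5, sd = 1),
                         speed_ar = 0.6,
                         transit_turn_sd = 2, fishing_turn_sd = 25,
                         fishing_dwell = 170, transit_dwell = 4,
                         end_leg = 60, trip_hours = c(10, 16),
                         observer_coverage = 0.07, vms_interval = 60,
                         vtr_rule = c("first_haul", "last_haul", "max_catch"),
                         footprint_sd_km = 8,
                         haul_value_mean = 4000, haul_value_sd = 1200,
                         p_ais = 0.45, p_vms_no_ais = 0.62, p_vms_ais = 0.9,
                         ais_dropout = 0.03,
                         lon_range = c(-71.6, -69.9),
                         lat_range = c(40.0, 41.2),
                         port = c(-71.35, 41.15),
                         state_waters_lat = 41.05,
                         n_grounds = 4, ground_sd_km = 3,
                         n_leases = 4, lease_km = 10,
                         years = 2015:2018) {
  vtr_rule <- match.arg(vtr_rule)
  stopifnot(transit_speed["sd"] >= 0, fishing_speed["sd"] >= 0,
            observer_coverage >= 0, observer_coverage <= 1,
            diff(lon_range) > 0, diff(lat_range) > 0,
            trip_hours[1] > 0, trip_hours[2] >= trip_hours[1])
  structure(as.list(environment()), class = "fleet_config")
}

# local equirectangular plane centered on the study area; metres
plane_of <- function(config) {
  lat0 <- mean(config$lat_range)
  lon0 <- mean(config$lon_range)
  R <- 6371000
  list(
    to_lonlat = function(x, y) {
      cbind(lon = lon0 + x / (R * cos(lat0 * pi / 180)) * 180 / pi,
            lat = lat0 + y / R * 180 / pi)
    },
    to_xy = function(lon, lat) {
      cbind(x = (lon - lon0) * pi / 180 * R * cos(lat0 * pi / 180),
            y = (lat - lat0) * pi / 180 * R)
    }
  )
}

KNOT_M_PER_MIN <- 1852 / 60

#' Simulate a synthetic scallop fleet
#'
#' Generates ground-truth vessel behavior — a two-state semi-Markov
#' trajectory per trip with exponential dwell times, correlated random-walk
#' headings (state-specific turn SD) and AR(1) speeds around the
#' state means — together with every degraded observation product the
#' pipeline consumes: 1-minute AIS pings with dropout, interval-subsampled
#' VMS polls, an observer-covered subset of hauls, a single (biased) VTR
#' point and landed value per trip, plus lease/exclusion polygons, a
#' bathymetry grid and a moon-illumination table.
#'
#' @param config A [fleet_config()].
#' @param seed Integer seed; the same seed reproduces the fleet bit for
#'   bit.
#' @return A list with elements `truth` (`pings` with the true state,
#'   `hauls`, `trips`), `ais`, `vms`, `vtr`, `hauls_observed`,
#'   `availability`, `leases`, `exclusion`, `bathy`, `moon` and `config`.
#' @export
simulate_fleet <- function(config = fleet_config(), seed = 1) {
  stopifnot(inherits(config, "fleet_config"))
  set.seed(seed)
  pl <- plane_of(config)
  port_xy <- pl$to_xy(config$port[1], config$port[2])
  # fishing grounds in the federal-waters middle of the area
  glon <- stats::runif(config$n_grounds,
                       config$lon_range[1] + 0.15 * diff(config$lon_range),
                       config$lon_range[1] + 0.55 * diff(config$lon_range))
  glat <- stats::runif(config$n_grounds,
                       config$state_waters_lat - 0.12,
                       config$state_waters_lat - 0.035)
  grounds <- pl$to_xy(glon, glat)

  vessels <- sprintf("V%02d", seq_len(config$n_vessels))
  has_ais <- stats::runif(config$n_vessels) < config$p_ais
  has_vms <- ifelse(has_ais,
                    stats::runif(config$n_vessels) < config$p_vms_ais,
                    stats::runif(config$n_vessels) < config$p_vms_no_ais)

  day_pool <- seq(as.Date(paste0(min(config$years), "-01-01")),
                  as.Date(paste0(max(config$years), "-12-31")), by = "day")
  ping_list <- list()
  haul_list <- list()
  trip_rows <- list()
  for (vi in seq_len(config$n_vessels)) {
    days <- sort(sample(day_pool, config$trips_per_vessel))
    for (ti in seq_len(config$trips_per_vessel)) {
      trip_id <- sprintf("%s-T%02d", vessels[vi], ti)
      t0 <- as.POSIXct(days[ti], tz = "UTC") +
        60 * sample.int(8 * 60, 1)  # depart between 00:01 and 08:00 UTC
      dur <- round(stats::runif(1, config$trip_hours[1],
                                config$trip_hours[2]) * 60)
      tr <- simulate_trip(config, pl, port_xy, grounds, dur)
      ll <- pl$to_lonlat(tr$x, tr$y)
      ts <- t0 + 60 * (seq_len(dur) - 1)
      ping_list[[trip_id]] <- data.frame(
        vessel_id = vessels[vi], trip_id = trip_id, timestamp = ts,
        lat = ll[, 2], lon = ll[, 1], sog = tr$sog, cog = tr$cog,
        source = "AIS", interpolated = FALSE, state = tr$state,
        stringsAsFactors = FALSE)
      # hauls = maximal runs of the fishing state
      r <- rle(tr$state == "fishing")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      fi <- which(r$values)
      n_hauls <- length(fi)
      if (n_hauls) {
        haul_list[[trip_id]] <- data.frame(
          trip_id = trip_id,
          start = ts[starts[fi]], end = ts[ends[fi]],
          start_lat = ll[starts[fi], 2], start_lon = ll[starts[fi], 1],
          end_lat = ll[ends[fi], 2], end_lon = ll[ends[fi], 1],
          value = pmax(stats::rnorm(n_hauls, config$haul_value_mean,
                                    config$haul_value_sd), 200),
          stringsAsFactors = FALSE)
      }
      trip_rows[[trip_id]] <- data.frame(
        trip_id = trip_id, vessel_id = vessels[vi],
        depart = ts[1], return = ts[dur],
        landed_value = if (n_hauls) sum(haul_list[[trip_id]]$value) else 0,
        stringsAsFactors = FALSE)
    }
  }
  truth_pings <- do.call(rbind, ping_list)
  rownames(truth_pings) <- NULL
  truth_hauls <- do.call(rbind, haul_list)
  rownames(truth_hauls) <- NULL
  trips <- do.call(rbind, trip_rows)
  rownames(trips) <- NULL

  vmap <- stats::setNames(seq_along(vessels), vessels)
  trips$has_ais <- has_ais[vmap[trips$vessel_id]]
  trips$has_vms <- has_vms[vmap[trips$vessel_id]]
  trips$observed <- trips$has_ais &
    stats::runif(nrow(trips)) < config$observer_coverage

  # AIS product: 1-minute pings with dropout (trip endpoints retained)
  ais <- truth_pings[truth_pings$trip_id %in%
                       trips$trip_id[trips$has_ais], , drop = FALSE]
  keep <- stats::runif(nrow(ais)) >= config$ais_dropout
  first_last <- !duplicated(ais$trip_id) |
    !duplicated(ais$trip_id, fromLast = TRUE)
  ais <- ais[keep | first_last, setdiff(names(ais), "state"), drop = FALSE]
  rownames(ais) <- NULL

  vms_src <- truth_pings[truth_pings$trip_id %in%
                           trips$trip_id[trips$has_vms], , drop = FALSE]
  vms <- degrade_to_vms(vms_src[, setdiff(names(vms_src), "state")],
                        config$vms_interval)

  vtr <- vtr_report(trips, truth_hauls, truth_pings, config$vtr_rule)
  hauls_observed <- truth_hauls[truth_hauls$trip_id %in%
                                  trips$trip_id[trips$observed],
                                setdiff(names(truth_hauls), "value"),
                                drop = FALSE]
  rownames(hauls_observed) <- NULL

  availability <- data.frame(
    trip_id = trips$trip_id,
    ais = trips$has_ais, vms = trips$has_vms, vtr = TRUE,
    stringsAsFactors = FALSE)

  lease_half <- config$lease_km * 500  # half-edge in metres
  leases <- list()
  for (i in seq_len(config$n_leases)) {
    g <- grounds[((i - 1) %% config$n_grounds) + 1, , drop = FALSE]
    off <- if (i > config$n_grounds) c(1.5, -1.5) * lease_half else c(0, 0)
    cx <- g[1] + off[1]
    cy <- g[2] + off[2]
    sq <- rbind(c(cx - lease_half, cy - lease_half),
                c(cx + lease_half, cy - lease_half),
                c(cx + lease_half, cy + lease_half),
                c(cx - lease_half, cy + lease_half),
                c(cx - lease_half, cy - lease_half))
    ring <- pl$to_lonlat(sq[, 1], sq[, 2])
    leases[[sprintf("LEASE-%02d", i)]] <- list(ring)
  }
  leases <- as_polygon_set(leases)

  excl_ring <- cbind(
    lon = c(config$lon_range[1], config$lon_range[2], config$lon_range[2],
            config$lon_range[1], config$lon_range[1]),
    lat = c(config$state_waters_lat, config$state_waters_lat,
            config$lat_range[2] + 0.1, config$lat_range[2] + 0.1,
            config$state_waters_lat))
  exclusion <- as_polygon_set(list(state_waters = list(excl_ring)))

  list(truth = list(pings = truth_pings, hauls = truth_hauls, trips = trips),
       ais = ais, vms = vms, vtr = vtr, hauls_observed = hauls_observed,
       availability = availability, leases = leases, exclusion = exclusion,
       bathy = synthetic_bathymetry(config), moon = synthetic_moon(config),
       config = config, seed = seed)
}

# one trip's minute-resolution walk in plane coordinates
simulate_trip <- function(config, pl, port_xy, grounds, dur) {
  gi <- sample.int(nrow(grounds), 1)
  # tow targets stay south of the state-waters line: the fishery operates
  # under the federal plan and does not dredge across the jurisdiction line
  y_cap <- pl$to_xy(config$port[1], config$state_waters_lat)[2] - 2500
  new_target <- function() {
    tg <- grounds[gi, ] + stats::rnorm(2, 0, config$ground_sd_km * 1000)
    tg[2] <- min(tg[2], y_cap)
    tg
  }
  target <- new_target()
  x <- numeric(dur); y <- numeric(dur)
  sog <- numeric(dur); cog <- numeric(dur)
  state <- character(dur)
  pos <- c(port_xy[1], port_xy[2]) + stats::rnorm(2, 0, 500)
  mode <- "outbound"
  cur <- "transit"
  dwell <- Inf
  v <- stats::rnorm(1, config$transit_speed["mean"],
                    config$transit_speed["sd"])
  psi <- bearing_to(pos, target)
  ar <- config$speed_ar
  for (t in seq_len(dur)) {
    if (mode != "inbound" && t > dur - config$end_leg) {
      mode <- "inbound"
      if (cur == "fishing") {
        cur <- "transit"
        v <- stats::rnorm(1, config$transit_speed["mean"],
                          config$transit_speed["sd"])
      }
    }
    if (mode == "outbound") {
      d <- sqrt(sum((pos - target)^2))
      if (d < 2000 || t > 300) {
        mode <- "grounds"
        cur <- "fishing"
        dwell <- max(20, stats::rexp(1, 1 / config$fishing_dwell))
        v <- stats::rnorm(1, config$fishing_speed["mean"],
                          config$fishing_speed["sd"])
      }
    } else if (mode == "grounds") {
      dwell <- dwell - 1
      if (dwell <= 0) {
        if (cur == "fishing") {
          cur <- "transit"
          dwell <- max(3, stats::rexp(1, 1 / config$transit_dwell))
          target <- new_target()
          v <- stats::rnorm(1, config$transit_speed["mean"],
                            config$transit_speed["sd"])
        } else {
          cur <- "fishing"
          dwell <- max(20, stats::rexp(1, 1 / config$fishing_dwell))
          v <- stats::rnorm(1, config$fishing_speed["mean"],
                            config$fishing_speed["sd"])
        }
      }
    }
    sp <- if (cur == "fishing") config$fishing_speed else config$transit_speed
    v <- sp["mean"] + ar * (v - sp["mean"]) +
      stats::rnorm(1, 0, sp["sd"] * sqrt(1 - ar^2))
    v <- max(v, 0.2)
    if (cur == "transit") {
      goal <- if (mode == "inbound") port_xy else target
      turn <- heading_change(psi, bearing_to(pos, goal))
      psi <- psi + pmin(pmax(turn, -20), 20) +
        stats::rnorm(1, 0, config$transit_turn_sd)
    } else {
      # weak tether toward the ground center keeps tow bouts on the bed
      pull <- heading_change(psi, bearing_to(pos, target))
      psi <- psi + pmin(pmax(0.2 * pull, -5), 5) +
        stats::rnorm(1, 0, config$fishing_turn_sd)
    }
    step <- v * KNOT_M_PER_MIN
    pos <- pos + step * c(sin(psi * pi / 180), cos(psi * pi / 180))
    x[t] <- pos[1]; y[t] <- pos[2]
    sog[t] <- v; cog[t] <- psi %% 360
    state[t] <- cur
  }
  list(x = x, y = y, sog = round(sog, 2), cog = round(cog, 1), state = state)
}

bearing_to <- function(pos, goal) {
  atan2(goal[1] - pos[1], goal[2] - pos[2]) * 180 / pi
}

vtr_report <- function(trips, hauls, pings, rule) {
  rows <- lapply(seq_len(nrow(trips)), function(i) {
    tid <- trips$trip_id[i]
    h <- hauls[hauls$trip_id == tid, , drop = FALSE]
    if (nrow(h)) {
      j <- switch(rule,
                  first_haul = which.min(h$start),
                  last_haul = which.max(h$start),
                  max_catch = which.max(h$value))
      lat <- h$start_lat[j]; lon <- h$start_lon[j]
    } else {
      p <- pings[pings$trip_id == tid, , drop = FALSE]
      mid <- ceiling(nrow(p) / 2)
      lat <- p$lat[mid]; lon <- p$lon[mid]
    }
    data.frame(trip_id = tid, reported_lat = lat, reported_lon = lon,
               landed_value = trips$landed_value[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subsample 1-minute pings to VMS poll resolution
#'
#' Keeps the first ping of each poll-interval bin (bins anchored at each
#' trip's first ping) and relabels the source `"VMS"`.
#'
#' @param pings 1-minute pings with `trip_id`.
#' @param interval Poll interval in minutes.
#' @return Subsampled ping data frame.
#' @export
degrade_to_vms <- function(pings, interval = 60) {
  if (!nrow(pings)) {
    pings$source <- character(0)
    return(pings)
  }
  keep <- unlist(lapply(split(seq_len(nrow(pings)), pings$trip_id),
                        function(idx) {
    tt <- as.numeric(pings$timestamp[idx])
    bin <- floor((tt - tt[1]) / (interval * 60))
    idx[!duplicated(bin)]
  }), use.names = FALSE)
  out <- pings[sort(keep), , drop = FALSE]
  out$source <- "VMS"
  rownames(out) <- NULL
  out
}

# smooth shelf bathymetry: deeper southward/offshore, gentle ridges
synthetic_bathymetry <- function(config, cell_deg = 0.01) {
  nx <- ceiling(diff(config$lon_range) / cell_deg)
  ny <- ceiling(diff(config$lat_range) / cell_deg)
  spec <- grid_spec(config$lon_range[1], config$lat_range[1], nx, ny,
                    cell_deg, proj = NULL, snap = FALSE)
  cc <- cell_centers(spec)
  frac_off <- (config$lat_range[2] - cc$y) / diff(config$lat_range)
  depth <- 20 + 80 * frac_off +
    6 * sin(cc$x * 40) * cos(cc$y * 55)
  value_grid(spec, depth)
}

# synodic-cycle illumination table (percent of disk, by UTC date)
synthetic_moon <- function(config) {
  dates <- seq(as.Date(paste0(min(config$years) - 1, "-12-01")),
               as.Date(paste0(max(config$years) + 1, "-01-31")), by = "day")
  phase <- as.numeric(dates - as.Date("2015-01-20")) / 29.530589
  data.frame(date = dates,
             percent_illuminated =
               round(50 * (1 - cos(2 * pi * phase)), 2))
}

#' Write a simulated fleet to disk in the package's file dialects
#'
#' Tracks, trips, observed hauls and VTR reports as headered CSV; the moon
#' table as CSV; bathymetry as an ASCII grid; lease and exclusion polygons
#' as GeoJSON — exactly the dialects the reader functions consume.
#'
#' @param fleet A fleet from [simulate_fleet()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fleet <- function(fleet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) {
    for (cl in names(d)) {
      if (inherits(d[[cl]], "POSIXct"))
        d[[cl]] <- format(d[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  wcsv(fleet$ais[, c("vessel_id", "timestamp", "lat", "lon", "sog", "cog")],
       "ais.csv")
  wcsv(fleet$vms[, c("vessel_id", "timestamp", "lat", "lon", "sog", "cog")],
       "vms.csv")
  wcsv(fleet$truth$trips[, c("trip_id", "vessel_id", "depart", "return",
                             "landed_value")], "trips.csv")
  wcsv(fleet$hauls_observed, "hauls.csv")
  wcsv(fleet$vtr, "vtr.csv")
  wcsv(fleet$availability, "availability.csv")
  utils::write.csv(fleet$moon, file.path(dir, "moon.csv"),
                   row.names = FALSE)
  write_ascii_grid(fleet$bathy, file.path(dir, "bathy.asc"), digits = 6)
  write_polygons(fleet$leases, file.path(dir, "leases.geojson"))
  write_polygons(fleet$exclusion, file.path(dir, "exclusion.geojson"))
  invisible(dir)
}
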