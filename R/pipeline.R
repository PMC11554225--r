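#' Read a fleet directory written by [write_fleet()]
#'
#' @param dir Directory holding `ais.csv`, `vms.csv`, `trips.csv`,
#'   `hauls.csv`, `vtr.csv`, `availability.csv`, `moon.csv`, `bathy.asc`,
#'   `leases.geojson`, `exclusion.geojson`.
#' @return A fleet-shaped list usable by [run_pipeline()].
#' @export
read_fleet <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("ais.csv", "trips.csv", "vtr.csv"))
    if (!file.exists(path(f))) stop("missing input file: ", f)
  avail <- utils::read.csv(path("availability.csv"),
                           stringsAsFactors = FALSE)
  for (cl in c("ais", "vms", "vtr")) avail[[cl]] <- as.logical(avail[[cl]])
  list(
    ais = read_tracks(path("ais.csv"), "AIS"),
    vms = if (file.exists(path("vms.csv")))
      read_tracks(path("vms.csv"), "VMS") else NULL,
    truth = list(trips = read_trips(path("trips.csv"))),
    hauls_observed = read_hauls(path("hauls.csv")),
    vtr = read_vtr_reports(path("vtr.csv")),
    availability = avail,
    moon = read_moon_table(path("moon.csv")),
    bathy = read_ascii_grid(path("bathy.asc")),
    leases = read_polygons(path("leases.geojson")),
    exclusion = read_polygons(path("exclusion.geojson"))
  )
}

#' Run the full exposure pipeline
#'
#' Orchestrates ingest, state-waters masking, 1-minute resampling, feature
#' engineering, observer labeling, forest training (or reuse of a supplied
#' model), prediction, stepwise AIS/VMS/VTR triage with fallback demotion,
#' per-tier value distribution, 500 m rasterization by year, raster
#' combination and lease-area summaries.
#'
#' @param fleet A fleet list from [simulate_fleet()] or [read_fleet()].
#' @param cellsize Exposure grid cell size, metres (default 500).
#' @param n_trees,max_depth,min_node Forest configuration used when no
#'   `model` is supplied.
#' @param model Optional pre-fitted `"fishing_forest"`.
#' @param features Candidate feature names (default [candidate_features()];
#'   depth/moon features are dropped automatically when bathymetry or the
#'   moon table are absent).
#' @param cutoff VMS speed cutoff, knots.
#' @param footprint_sd_km Footprint kernel SD for the VTR tier.
#' @param seed Integer seed (forest growth and fold assignment).
#' @param min_pings Minimum window occupancy for valid features.
#' @return A list with `model`, `tiers`, `value_points`, `rasters` (per
#'   year), `combined`, `lease_summary`, `train_metrics` and `manifest`.
#' @export
run_pipeline <- function(fleet, cellsize = 500, n_trees = 300,
                         max_depth = Inf, min_node = 1, model = NULL,
                         features = candidate_features(), cutoff = 5,
                         footprint_sd_km = NULL, seed = 1, min_pings = 5) {
  trips <- fleet$truth$trips
  if (is.null(footprint_sd_km))
    footprint_sd_km <- fleet$config$footprint_sd_km %||% 8
  counts <- list(seed = seed)

  ais <- mask_exclusion_zone(fleet$ais, fleet$exclusion)
  counts$ais_pings_masked <- attr(ais, "n_removed")
  if (!is.null(ais) && anyNA(ais$trip_id)) ais <- link_trips(ais, trips)
  ais <- ais[!is.na(ais$trip_id), , drop = FALSE]
  counts$ais_pings <- nrow(ais)

  if (is.null(fleet$bathy))
    features <- setdiff(features, c("depth_avg", "depth_std"))
  if (is.null(fleet$moon)) features <- setdiff(features, "moon")
  fml <- stats::reformulate(features, "fishing")
  train_metrics <- NULL
  if (nrow(ais)) {
    res <- resample_tracks(ais)
    feats <- window_features(res, min_pings = min_pings,
                             bathy = fleet$bathy, moon = fleet$moon)
    counts$feature_rows <- sum(feats$valid)
    labeled <- label_fishing(feats, fleet$hauls_observed, trips)
    train <- labeled[labeled$valid & !is.na(labeled$fishing), ,
                     drop = FALSE]
    counts$labeled_pings <- nrow(train)
    if (is.null(model)) {
      if (length(unique(train$fishing)) < 2) {
        warning("no two-class training data; AIS trips fall back")
      } else {
        model <- fishing_forest(fml, train, n_trees = n_trees,
                                max_depth = max_depth,
                                min_node = min_node, seed = seed)
      }
    }
    if (!is.null(model)) {
      if (nrow(train))
        train_metrics <- classification_metrics(
          train$fishing, predict(model, train)$fishing)
      pred <- rep(FALSE, nrow(feats))
      pred[feats$valid] <- predict(
        model, feats[feats$valid, , drop = FALSE])$fishing
      feats$pred_fishing <- pred & feats$valid
    } else {
      feats$pred_fishing <- FALSE
    }
  } else {
    feats <- NULL
    counts$feature_rows <- 0L
    counts$labeled_pings <- 0L
  }

  avail <- fleet$availability
  with_feats <- if (is.null(feats)) character(0)
                else unique(feats$trip_id[feats$valid])
  avail$ais <- avail$ais & avail$trip_id %in% with_feats &
    !is.null(model)
  tri <- triage(avail)
  tier <- stats::setNames(tri$assignment$tier, tri$assignment$trip_id)

  vms <- fleet$vms
  if (!is.null(vms) && anyNA(vms$trip_id)) vms <- link_trips(vms, trips)

  value_points <- list()
  demotions <- character(0)
  for (tid in names(tier)) {
    trip <- trips[trips$trip_id == tid, , drop = FALSE]
    if (tier[[tid]] == "AIS") {
      fp <- feats[feats$trip_id == tid & feats$pred_fishing, , drop = FALSE]
      vp <- distribute_value(trip, fp)
      if (isTRUE(attr(vp, "fallback"))) {
        tier[[tid]] <- demote_tier("AIS", avail[avail$trip_id == tid, ])
        demotions <- c(demotions, tid)
      } else {
        value_points[[tid]] <- vp
      }
    }
    if (tier[[tid]] == "VMS") {
      polls <- vms[!is.na(vms$trip_id) & vms$trip_id == tid, , drop = FALSE]
      fp <- polls[speed_cutoff(polls$sog, cutoff), , drop = FALSE]
      vp <- distribute_value(trip, fp)
      if (isTRUE(attr(vp, "fallback"))) {
        tier[[tid]] <- "VTR"
        demotions <- c(demotions, tid)
      } else {
        value_points[[tid]] <- vp
      }
    }
  }
  counts$demotions <- length(unique(demotions))
  counts$tier_ais <- sum(tier == "AIS")
  counts$tier_vms <- sum(tier == "VMS")
  counts$tier_vtr <- sum(tier == "VTR")

  pts <- do.call(rbind, value_points)
  vtr_trips <- names(tier)[tier == "VTR"]
  vtr <- fleet$vtr[fleet$vtr$trip_id %in% vtr_trips, , drop = FALSE]
  all_lon <- c(pts$lon, vtr$reported_lon)
  all_lat <- c(pts$lat, vtr$reported_lat)
  spec <- grid_for_points(all_lon, all_lat, cellsize,
                          margin = 4 * footprint_sd_km * 1000 + 2 * cellsize)

  year_of <- stats::setNames(format(trips$depart, "%Y"), trips$trip_id)
  years <- sort(unique(year_of[names(tier)]))
  rasters <- list()
  empty_pts <- data.frame(trip_id = character(0), lat = numeric(0),
                          lon = numeric(0), dollars = numeric(0))
  for (yr in years) {
    pyr <- if (is.null(pts) || !nrow(pts)) empty_pts
           else pts[year_of[pts$trip_id] == yr, , drop = FALSE]
    g <- rasterize_points(pyr, spec)
    acc <- g$values
    for (tid in vtr_trips[year_of[vtr_trips] == yr]) {
      vrow <- vtr[vtr$trip_id == tid, , drop = FALSE]
      if (!nrow(vrow) || vrow$landed_value <= 0) next
      fp <- gaussian_footprint(spec, vrow$reported_lon, vrow$reported_lat,
                               footprint_sd_km)
      acc <- acc + footprint_value(fp, vrow$landed_value)$values
    }
    rasters[[yr]] <- value_grid(spec, acc)
  }
  combined <- combine_rasters(rasters)
  lease_summary <- lease_exposure(rasters, fleet$leases)

  counts$total_landed <- sum(trips$landed_value[trips$trip_id %in%
                                                  names(tier)])
  counts$total_rasterized <- sum(combined$values)
  counts$conservation_ratio <-
    if (counts$total_landed > 0)
      counts$total_rasterized / counts$total_landed else 1

  list(model = model, features = feats, tiers = tier,
       value_points = value_points, rasters = rasters, combined = combined,
       lease_summary = lease_summary, train_metrics = train_metrics,
       manifest = counts)
}
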