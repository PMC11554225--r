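#' Stepwise source triage of trips
#'
#' Assigns every trip to exactly one data tier by fixed priority: AIS when
#' available, else VMS, else VTR, so a trip contributes value from exactly
#' one source and is never double counted.
#'
#' @param availability Data frame with columns `trip_id` and logical `ais`,
#'   `vms`, `vtr` availability flags.
#' @return List with `assignment` (data frame `trip_id`, `tier`) and
#'   `coverage` (data frame `source`, `n_trips`, `percent`, percents of the
#'   total rounded to 2 decimals).
#' @export
triage <- function(availability) {
  stopifnot(all(c("trip_id", "ais", "vms", "vtr") %in% names(availability)))
  none <- !(availability$ais | availability$vms | availability$vtr)
  if (any(none))
    stop("trip(s) available in no source: ",
         paste(availability$trip_id[none], collapse = ", "))
  tier <- ifelse(availability$ais, "AIS",
                 ifelse(availability$vms, "VMS", "VTR"))
  n <- c(AIS = sum(tier == "AIS"), VMS = sum(tier == "VMS"),
         VTR = sum(tier == "VTR"))
  list(
    assignment = data.frame(trip_id = availability$trip_id, tier = tier,
                            stringsAsFactors = FALSE),
    coverage = data.frame(
      source = names(n), n_trips = as.integer(n),
      percent = round(100 * n / sum(n), 2), row.names = NULL,
      stringsAsFactors = FALSE)
  )
}

#' Demote a trip's tier after a fallback signal
#'
#' Used when an AIS-tier trip yields zero fishing pings (or a VMS-tier trip
#' zero fishing polls): the trip falls to the next available source so its
#' landed value is not lost.
#' @param tier Current tier, `"AIS"` or `"VMS"`.
#' @param available Availability row (logical `vms`, `vtr`).
#' @return The next tier.
#' @keywords internal
demote_tier <- function(tier, available) {
  if (tier == "AIS" && isTRUE(available[["vms"]])) "VMS" else "VTR"
}

#' Distribute a trip's landed value over its fishing locations
#'
#' The trip's ex-vessel value is split evenly over the n fishing pings:
#' each receives `landed_value / n`. With zero fishing pings the result is
#' empty and flagged (`attr "fallback" = TRUE`) so triage can demote the
#' trip to the next data source.
#'
#' @param trip One-row trip data frame (`trip_id`, `landed_value`).
#' @param fishing_pings Data frame of the trip's fishing locations (`lat`,
#'   `lon`).
#' @return Data frame `trip_id, lat, lon, dollars`; dollars sum to
#'   `landed_value` (exactly, up to float rounding).
#' @export
distribute_value <- function(trip, fishing_pings) {
  stopifnot(nrow(trip) == 1, trip$landed_value >= 0)
  n <- nrow(fishing_pings)
  if (n == 0) {
    out <- data.frame(trip_id = character(0), lat = numeric(0),
                      lon = numeric(0), dollars = numeric(0))
    attr(out, "fallback") <- TRUE
    return(out)
  }
  data.frame(trip_id = trip$trip_id, lat = fishing_pings$lat,
             lon = fishing_pings$lon, dollars = trip$landed_value / n,
             stringsAsFactors = FALSE)
}

#' Value a fishing-footprint probability raster
#'
#' Multiplies a per-trip fishing-probability raster (cells summing to 1) by
#' the trip's landed value; the result sums to the trip value.
#'
#' @param footprint A `"value_grid"` of probabilities.
#' @param trip_value Landed ex-vessel value, USD.
#' @return A `"value_grid"` of dollars.
#' @export
footprint_value <- function(footprint, trip_value) {
  stopifnot(inherits(footprint, "value_grid"), trip_value >= 0)
  s <- sum(footprint$values, na.rm = TRUE)
  if (abs(s - 1) > 1e-3)
    stop(sprintf("malformed footprint: probabilities sum to %.6f", s))
  value_grid(footprint$spec, footprint$values / s * trip_value)
}

#' Build a Gaussian fishing footprint around a reported location
#'
#' Discretized isotropic Gaussian centered on the VTR-reported point,
#' evaluated at cell centers within 4 SD and normalized to sum to 1. This is
#' the package's synthetic stand-in for externally modeled footprint
#' rasters, which are otherwise consumed as inputs.
#'
#' @param spec Target `"grid_spec"` (projected).
#' @param lon,lat Reported location, degrees.
#' @param sd_km Kernel standard deviation in km.
#' @return A `"value_grid"` of probabilities summing to 1.
#' @export
gaussian_footprint <- function(spec, lon, lat, sd_km) {
  stopifnot(sd_km > 0)
  ctr <- project_points(lon, lat, spec$proj)
  sd_m <- sd_km * 1000
  cs <- spec$cellsize
  # evaluate only within the 4-sd bounding box
  c0 <- max(1L, floor((ctr[1] - 4 * sd_m - spec$xmin) / cs) + 1)
  c1 <- min(spec$nx, floor((ctr[1] + 4 * sd_m - spec$xmin) / cs) + 1)
  r0 <- max(1L, floor((ctr[2] - 4 * sd_m - spec$ymin) / cs) + 1)
  r1 <- min(spec$ny, floor((ctr[2] + 4 * sd_m - spec$ymin) / cs) + 1)
  v <- matrix(0, spec$ny, spec$nx)
  if (c0 <= c1 && r0 <= r1) {
    cx <- spec$xmin + (c0:c1 - 0.5) * cs
    cy <- spec$ymin + (r0:r1 - 0.5) * cs
    d2 <- outer((cy - ctr[2])^2, (cx - ctr[1])^2, `+`)
    v[r0:r1, c0:c1] <- exp(-d2 / (2 * sd_m^2))
  }
  tot <- sum(v)
  if (tot <= 0) {
    # center off-grid: place all mass in the nearest cell
    ci <- cell_index(spec, min(max(ctr[1], spec$xmin), spec$xmin +
                                 (spec$nx - 0.5) * cs),
                     min(max(ctr[2], spec$ymin), spec$ymin +
                           (spec$ny - 0.5) * cs))
    v[ci$row, ci$col] <- 1
    tot <- 1
  }
  value_grid(spec, v / tot)
}

#' Sum raster exposure inside lease polygons
#'
#' Sums cell values whose centers fall inside each lease polygon. With one
#' raster (or one per year) the result is a `lease x year` table; when a
#' second product is supplied a `difference_usd` column (first minus
#' second, i.e. AIS-derived minus footprint-derived) is appended.
#'
#' @param raster A `"value_grid"`, or a named list of them (names = years).
#' @param leases A `"polygon_set"` in lon/lat.
#' @param raster_b Optional comparison product, same shape as `raster`.
#' @param names_ab Column names for the two products.
#' @return Data frame `lease_id, year, ais_usd[, vtr_usd, difference_usd]`.
#' @export
lease_exposure <- function(raster, leases, raster_b = NULL,
                           names_ab = c("ais_usd", "vtr_usd")) {
  leases <- as_polygon_set(leases)
  rl <- if (inherits(raster, "value_grid")) list(all = raster) else raster
  bl <- if (is.null(raster_b)) NULL
        else if (inherits(raster_b, "value_grid")) list(all = raster_b)
        else raster_b
  spec <- rl[[1]]$spec
  for (g in c(rl, bl)) {
    if (!same_grid(spec, g$spec))
      stop("lease_exposure: rasters must share one grid definition")
  }
  rows <- list()
  for (ln in names(leases)) {
    mask <- polygon_cell_mask(spec, leases[[ln]])
    for (yr in names(rl)) {
      a <- sum(rl[[yr]]$values[mask], na.rm = TRUE)
      row <- data.frame(lease_id = ln, year = yr, a = a,
                        stringsAsFactors = FALSE)
      names(row)[3] <- names_ab[1]
      if (!is.null(bl)) {
        b <- sum(bl[[yr]]$values[mask], na.rm = TRUE)
        row[[names_ab[2]]] <- b
        row$difference_usd <- a - b
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
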