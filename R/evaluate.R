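#' Accuracy of the speed-cutoff rule against observer labels
#'
#' Proportion of locations where the cutoff rule agrees with the
#' observer-verified fishing state.
#'
#' @param sog Speed over ground, knots.
#' @param fishing Logical observer truth.
#' @param cutoff Cutoff in knots (default 5).
#' @return Fraction correct in `[0, 1]`.
#' @export
cutoff_accuracy <- function(sog, fishing, cutoff = 5) {
  if (!length(sog)) stop("no locations supplied")
  if (length(sog) != length(fishing)) stop("length mismatch")
  mean(speed_cutoff(sog, cutoff) == as.logical(fishing))
}

# Cells a segment passes through (grid traversal, Amanatides & Woo).
# Coordinates in grid CRS units. Returns matrix with columns row, col,
# restricted to cells inside the grid.
segment_cells <- function(spec, x0, y0, x1, y1) {
  cs <- spec$cellsize
  fx0 <- (x0 - spec$xmin) / cs
  fy0 <- (y0 - spec$ymin) / cs
  fx1 <- (x1 - spec$xmin) / cs
  fy1 <- (y1 - spec$ymin) / cs
  ix <- floor(fx0); iy <- floor(fy0)
  ix_end <- floor(fx1); iy_end <- floor(fy1)
  dx <- fx1 - fx0; dy <- fy1 - fy0
  step_x <- sign(dx); step_y <- sign(dy)
  tdx <- if (dx != 0) abs(1 / dx) else Inf
  tdy <- if (dy != 0) abs(1 / dy) else Inf
  tmx <- if (dx > 0) (ix + 1 - fx0) / dx else if (dx < 0) (ix - fx0) / dx else Inf
  tmy <- if (dy > 0) (iy + 1 - fy0) / dy else if (dy < 0) (iy - fy0) / dy else Inf
  cells <- matrix(NA_integer_, abs(ix_end - ix) + abs(iy_end - iy) + 1, 2)
  k <- 1L
  cells[k, ] <- c(iy, ix)
  while ((ix != ix_end || iy != iy_end) && k < nrow(cells)) {
    if (tmx < tmy) {
      ix <- ix + step_x
      tmx <- tmx + tdx
    } else {
      iy <- iy + step_y
      tmy <- tmy + tdy
    }
    k <- k + 1L
    cells[k, ] <- c(iy, ix)
  }
  cells <- cells[seq_len(k), , drop = FALSE] + 1L  # to 1-based row, col
  ok <- cells[, 1] >= 1 & cells[, 1] <= spec$ny &
    cells[, 2] >= 1 & cells[, 2] <= spec$nx
  cells[ok, , drop = FALSE]
}

#' Binary raster of observed haul lines
#'
#' Plots each haul as a straight segment from its start to end position and
#' marks every grid cell the segment passes through with 1 (0 elsewhere).
#'
#' @param hauls Haul data frame (`start_lat`, `start_lon`, `end_lat`,
#'   `end_lon`).
#' @param spec Target `"grid_spec"` (projected).
#' @return A binary `"value_grid"`.
#' @export
haul_raster <- function(hauls, spec) {
  vg <- value_grid(spec)
  if (!nrow(hauls)) return(vg)
  p0 <- project_points(hauls$start_lon, hauls$start_lat, spec$proj)
  p1 <- project_points(hauls$end_lon, hauls$end_lat, spec$proj)
  for (i in seq_len(nrow(hauls))) {
    cells <- segment_cells(spec, p0[i, 1], p0[i, 2], p1[i, 1], p1[i, 2])
    if (nrow(cells)) vg$values[cells] <- 1
  }
  vg
}

#' Footprint accuracy by trip-level regression
#'
#' Regresses the binary haul indicator (1 = cell crossed by an observed
#' haul) on the footprint's fishing probability for each cell, with no
#' intercept. The predictor is rescaled by the number of haul cells, i.e.
#' divided by the probability a perfectly concentrated footprint (uniform
#' on exactly the haul cells) would put on each, so a perfect footprint
#' scores slope 1 and an entirely misplaced one 0, letting the fleet-mean
#' slope read as a fraction correct.
#'
#' @param footprint A probability `"value_grid"` (cells sum to 1).
#' @param hauls A binary haul `"value_grid"` on the same grid.
#' @return The slope coefficient; 0 when the haul raster is empty; `NA`
#'   (with a warning) for a zero-variance predictor.
#' @export
footprint_ols <- function(footprint, hauls) {
  stopifnot(inherits(footprint, "value_grid"), inherits(hauls, "value_grid"))
  if (!same_grid(footprint$spec, hauls$spec)) stop("grid definitions differ")
  y <- as.vector(hauls$values)
  y[is.na(y)] <- 0
  n1 <- sum(y)
  if (n1 == 0) return(0)
  x <- as.vector(footprint$values) * n1
  x[is.na(x)] <- 0
  if (all(x == 0)) {
    warning("zero-variance footprint predictor; slope undefined")
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(y ~ x + 0)))
}

#' Fleet-mean footprint accuracy
#'
#' @param pairs List of `list(footprint =, hauls =)` pairs per trip.
#' @return Mean slope over trips with a defined slope.
#' @export
mean_footprint_ols <- function(pairs) {
  slopes <- vapply(pairs, function(p) {
    s <- footprint_ols(p$footprint, p$hauls)
    if (is.na(s)) NA_real_ else s
  }, 0)
  mean(slopes, na.rm = TRUE)
}

#' Kernel density of positive raster values inside a polygon
#'
#' Gaussian KDE (Scott's rule-of-thumb bandwidth, [stats::bw.nrd()]) of the
#' positive cell values whose centers fall inside the lease polygon. The
#' display masking of small values used in maps is a plotting choice, not
#' part of this statistic.
#'
#' @param raster A `"value_grid"`.
#' @param polygon Lease polygon in lon/lat.
#' @param n Number of density grid points.
#' @return A [stats::density] object (integrates to 1).
#' @export
cell_value_kde <- function(raster, polygon, n = 512) {
  mask <- polygon_cell_mask(raster$spec, polygon)
  vals <- raster$values[mask]
  vals <- vals[!is.na(vals) & vals > 0]
  if (length(vals) < 2)
    stop("need at least 2 positive cells inside the polygon")
  bw <- if (stats::sd(vals) > 0) stats::bw.nrd(vals)
        else max(abs(vals[1]), 1) * 0.01
  stats::density(vals, bw = bw, n = n)
}

#' Per-trip intrusion analysis of two exposure products
#'
#' For every trip carried by both products, compares the dollars each
#' product places inside each lease polygon. The per-lease difference is
#' footprint (VTR) minus point-based (AIS); a trip "matches" when all its
#' per-lease differences are below `match_tol` dollars in magnitude.
#' Summary statistics (mean, median, sample SD) are computed over the
#' per-trip net differences of the non-matching trips.
#'
#' @param point_products Named list (by trip) of valued-point data frames
#'   (`lon`, `lat`, `dollars`), the AIS-style product.
#' @param footprint_products Named list (by trip) of valued
#'   `"value_grid"`s, the VTR-style product.
#' @param leases A `"polygon_set"` in lon/lat.
#' @param spec Grid spec used for footprint lease sums (and for projecting
#'   points into lease polygons).
#' @param match_tol Dollar threshold for "same estimate" (default $0.01).
#' @return List with `differences` (trip x lease table with `ais_usd`,
#'   `vtr_usd`, `diff_usd = vtr - ais`), `per_trip` (net difference per
#'   trip) and `summary` (`percent_matching`, and `mean`, `median`, `sd`
#'   over differing trips; `NA` when every trip matches).
#' @export
intrusion_analysis <- function(point_products, footprint_products, leases,
                               spec, match_tol = 0.01) {
  trips <- intersect(names(point_products), names(footprint_products))
  if (!length(trips)) stop("no trips shared by the two products")
  leases <- as_polygon_set(leases)
  masks <- lapply(leases, function(p) polygon_cell_mask(spec, p))
  proj_leases <- lapply(leases, function(p)
    as_polygon_set(list(lapply(p, function(r)
      project_points(r[, 1], r[, 2], spec$proj)))))
  rows <- list()
  for (tid in trips) {
    pts <- point_products[[tid]]
    xy <- project_points(pts$lon, pts$lat, spec$proj)
    fp <- footprint_products[[tid]]
    if (!same_grid(fp$spec, spec)) stop("footprint grid mismatch: ", tid)
    for (ln in names(leases)) {
      inside <- points_in_polygon(xy[, 1], xy[, 2], proj_leases[[ln]],
                                  eps = 1e-6 * spec$cellsize) > 0
      a <- sum(pts$dollars[inside])
      b <- sum(fp$values[masks[[ln]]], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        trip_id = tid, lease_id = ln, ais_usd = a, vtr_usd = b,
        diff_usd = b - a, stringsAsFactors = FALSE)
    }
  }
  diffs <- do.call(rbind, rows)
  rownames(diffs) <- NULL
  net <- tapply(diffs$diff_usd, diffs$trip_id, sum)
  max_abs <- tapply(abs(diffs$diff_usd), diffs$trip_id, max)
  matching <- max_abs < match_tol
  differing <- net[!matching]
  summ <- list(
    percent_matching = 100 * mean(matching),
    n_trips = length(matching),
    mean = if (length(differing)) mean(differing) else NA_real_,
    median = if (length(differing)) stats::median(differing) else NA_real_,
    sd = if (length(differing) > 1) stats::sd(differing) else NA_real_
  )
  list(differences = diffs,
       per_trip = data.frame(trip_id = names(net),
                             net_diff_usd = as.numeric(net),
                             matching = as.logical(matching[names(net)]),
                             row.names = NULL, stringsAsFactors = FALSE),
       summary = summ)
}
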