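#' Define a raster grid
#'
#' A regular grid of square cells in a metric projected CRS (or, for
#' auxiliary grids such as bathymetry, in degrees with `proj = NULL`).
#' Cells are half-open, `[x, x + cellsize) x [y, y + cellsize)`, and the
#' origin is snapped down to a multiple of the cell size so that grids built
#' from different extents align.
#'
#' @param xmin,ymin Lower-left corner (snapped down to `cellsize` multiples
#'   when `snap = TRUE`).
#' @param nx,ny Number of columns / rows.
#' @param cellsize Cell edge length (metres for projected grids; default 500).
#' @param proj A `"utm_proj"` from [utm_proj()], or `NULL` for a grid in the
#'   input coordinate units.
#' @param snap Snap the origin to multiples of `cellsize` (default `TRUE` for
#'   projected grids).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(xmin, ymin, nx, ny, cellsize = 500, proj = NULL,
                      snap = !is.null(proj)) {
  stopifnot(nx >= 1, ny >= 1, cellsize > 0)
  if (snap) {
    xmin <- floor(xmin / cellsize) * cellsize
    ymin <- floor(ymin / cellsize) * cellsize
  }
  structure(list(xmin = xmin, ymin = ymin, nx = as.integer(nx),
                 ny = as.integer(ny), cellsize = cellsize, proj = proj),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d cells of %g, origin (%g, %g), %s\n",
              x$nx, x$ny, x$cellsize, x$xmin, x$ymin,
              if (is.null(x$proj)) "unprojected"
              else sprintf("UTM %d%s", x$proj$zone,
                           if (x$proj$north) "N" else "S")))
  invisible(x)
}

#' Build a grid covering lon/lat points
#'
#' Projects the points into the UTM zone of their centroid (unless `proj` is
#' given) and returns a snapped grid covering them with a margin.
#'
#' @param lon,lat Coordinates in degrees.
#' @param cellsize Cell size in metres.
#' @param margin Extra margin around the points, metres.
#' @param proj Optional projection override.
#' @export
grid_for_points <- function(lon, lat, cellsize = 500, margin = 2 * cellsize,
                            proj = NULL) {
  if (is.null(proj)) proj <- utm_proj(utm_zone(mean(range(lon))))
  xy <- project_utm(lon, lat, proj)
  xmin <- min(xy[, 1]) - margin
  ymin <- min(xy[, 2]) - margin
  xmin <- floor(xmin / cellsize) * cellsize
  ymin <- floor(ymin / cellsize) * cellsize
  nx <- ceiling((max(xy[, 1]) + margin - xmin) / cellsize)
  ny <- ceiling((max(xy[, 2]) + margin - ymin) / cellsize)
  grid_spec(xmin, ymin, nx, ny, cellsize, proj, snap = FALSE)
}

#' Create a value raster on a grid
#'
#' @param spec A `"grid_spec"`.
#' @param values Matrix of cell values, `ny` rows by `nx` columns, row 1 the
#'   *southernmost* row (y increases with row index). Default all zero.
#' @return An object of class `"value_grid"`.
#' @export
value_grid <- function(spec, values = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(values)) values <- matrix(0, spec$ny, spec$nx)
  values <- as.matrix(values)
  stopifnot(nrow(values) == spec$ny, ncol(values) == spec$nx)
  structure(list(spec = spec, values = values), class = "value_grid")
}

#' @export
print.value_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  print(x$spec)
  cat(sprintf("values: total %.4f, max %.4f, %d non-zero cells\n",
              sum(v), if (length(v)) max(v) else NA_real_, sum(v != 0)))
  invisible(x)
}

# Column/row indices of containing cells (half-open membership).
# Returns data.frame(col, row, inside).
cell_index <- function(spec, x, y) {
  col <- floor((x - spec$xmin) / spec$cellsize) + 1
  row <- floor((y - spec$ymin) / spec$cellsize) + 1
  inside <- col >= 1 & col <= spec$nx & row >= 1 & row <= spec$ny
  data.frame(col = col, row = row, inside = inside)
}

#' Cell-center coordinates of a grid
#' @param spec A `"grid_spec"`.
#' @return List with matrices `x` and `y` (`ny` by `nx`).
#' @export
cell_centers <- function(spec) {
  cx <- spec$xmin + (seq_len(spec$nx) - 0.5) * spec$cellsize
  cy <- spec$ymin + (seq_len(spec$ny) - 0.5) * spec$cellsize
  list(x = matrix(cx, spec$ny, spec$nx, byrow = TRUE),
       y = matrix(cy, spec$ny, spec$nx))
}

same_grid <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(a$xmin, b$xmin, tolerance = tol)) &&
    isTRUE(all.equal(a$ymin, b$ymin, tolerance = tol)) &&
    a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$cellsize, b$cellsize, tolerance = tol))
}

#' Sum point values into grid cells
#'
#' Each point's dollars are added to its containing half-open cell. Points
#' are given in lon/lat and projected with the grid's CRS; points falling
#' outside the grid extent are counted and reported via the
#' `"n_outside"`/`"outside_total"` attributes.
#'
#' @param points Data frame with columns `lon`, `lat`, `dollars` (or a
#'   `value` column named via `value_col`).
#' @param spec A `"grid_spec"`.
#' @param value_col Name of the value column (default `"dollars"`).
#' @return A `"value_grid"` of summed values.
#' @export
rasterize_points <- function(points, spec, value_col = "dollars") {
  stopifnot(all(c("lon", "lat", value_col) %in% names(points)))
  vg <- value_grid(spec)
  if (!nrow(points)) {
    attr(vg, "n_outside") <- 0L
    attr(vg, "outside_total") <- 0
    return(vg)
  }
  xy <- project_points(points$lon, points$lat, spec$proj)
  ci <- cell_index(spec, xy[, 1], xy[, 2])
  vals <- points[[value_col]]
  ok <- ci$inside
  if (any(ok)) {
    li <- (ci$col[ok] - 1) * spec$ny + ci$row[ok]
    sums <- rowsum(vals[ok], li)
    vg$values[as.integer(rownames(sums))] <- sums[, 1]
  }
  attr(vg, "n_outside") <- sum(!ok)
  attr(vg, "outside_total") <- sum(vals[!ok])
  vg
}

#' Add rasters cellwise
#'
#' Cellwise sum of rasters sharing one grid definition; `NA` cells are
#' treated as zero. Grid mismatch is an error.
#'
#' @param ... `"value_grid"` objects (or a single list of them).
#' @return A `"value_grid"`.
#' @export
combine_rasters <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "value_grid")) gs <- gs[[1]]
  stopifnot(length(gs) >= 1, all(vapply(gs, inherits, TRUE, "value_grid")))
  spec <- gs[[1]]$spec
  for (g in gs[-1]) {
    if (!same_grid(spec, g$spec)) stop("grid definitions differ; cannot combine")
  }
  acc <- matrix(0, spec$ny, spec$nx)
  for (g in gs) {
    v <- g$values
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  value_grid(spec, acc)
}

#' Cellwise difference of two rasters
#'
#' `A - B` on a shared grid. The sign convention is recorded in the
#' `"convention"` attribute of the result.
#'
#' @param a,b `"value_grid"` objects on identical grids.
#' @return A `"value_grid"` with attribute `convention = "A minus B"`.
#' @export
difference_raster <- function(a, b) {
  stopifnot(inherits(a, "value_grid"), inherits(b, "value_grid"))
  if (!same_grid(a$spec, b$spec)) stop("grid definitions differ")
  va <- a$values; va[is.na(va)] <- 0
  vb <- b$values; vb[is.na(vb)] <- 0
  out <- value_grid(a$spec, va - vb)
  attr(out, "convention") <- "A minus B"
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a 6-line header
#' followed by rows of values north to south. Used for exposure, footprint
#' and bathymetry rasters.
#'
#' @param grid A `"value_grid"`.
#' @param path Output path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "value_grid"))
  s <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$nx),
    paste("nrows", s$ny),
    paste("xllcorner", format(s$xmin, digits = 15)),
    paste("yllcorner", format(s$ymin, digits = 15)),
    paste("cellsize", format(s$cellsize, digits = 15)),
    "NODATA_value -9999"
  ), con)
  v <- grid$values
  v[is.na(v)] <- -9999
  # rows written north to south
  for (r in rev(seq_len(s$ny))) {
    writeLines(paste(format(v[r, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param proj Optional `"utm_proj"` to attach as the grid CRS.
#' @return A `"value_grid"`; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path, proj = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nx <- as.integer(vals["ncols"])
  ny <- as.integer(vals["nrows"])
  nodata <- if ("nodata_value" %in% keys) vals["nodata_value"] else -9999
  dat <- scan(path, skip = 6, quiet = TRUE)
  stopifnot(length(dat) == nx * ny)
  m <- matrix(dat, ny, nx, byrow = TRUE)
  m <- m[rev(seq_len(ny)), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA
  spec <- grid_spec(unname(vals["xllcorner"]), unname(vals["yllcorner"]),
                    nx, ny, unname(vals["cellsize"]), proj, snap = FALSE)
  value_grid(spec, m)
}

#' Mask of cells whose centers fall inside a polygon
#'
#' Polygon vertices are given in lon/lat and projected with the grid CRS;
#' membership is by cell center (boundary-touching centers count as inside).
#'
#' @param spec A `"grid_spec"` with a projection.
#' @param poly A polygon (list of ring matrices in lon/lat) or ring matrix.
#' @return Logical `ny` by `nx` matrix.
#' @export
polygon_cell_mask <- function(spec, poly) {
  poly <- as_polygon_set(poly)
  proj_poly <- lapply(poly, function(p) lapply(p, function(r) {
    project_points(r[, 1], r[, 2], spec$proj)
  }))
  cc <- cell_centers(spec)
  res <- points_in_polygon(as.vector(cc$x), as.vector(cc$y),
                           as_polygon_set(proj_poly),
                           eps = 1e-6 * spec$cellsize)
  matrix(res > 0L, spec$ny, spec$nx)
}
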