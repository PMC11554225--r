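#' Read polygons from GeoJSON
#'
#' Reads `Polygon` and `MultiPolygon` features (optionally inside a
#' `FeatureCollection`) into a plain list-of-polygons structure: each polygon
#' is a list of rings, each ring a closed two-column `lon`/`lat` matrix, the
#' first ring the outer boundary and the rest holes.
#'
#' @param path Path to a GeoJSON file.
#' @return A named list of class `"polygon_set"`; names come from feature
#'   `id`, `properties$name`, or `properties$lease_id` when present.
#' @export
read_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = ,
    MultiPolygon = list(list(geometry = g, properties = NULL)),
    stop("unsupported GeoJSON type: ", g$type)
  )
  polys <- list()
  nms <- character()
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    geom <- ft$geometry
    nm <- ft$properties$name %||% ft$properties$lease_id %||% ft$id %||%
      paste0("poly", i)
    ring_mat <- function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      m
    }
    add <- function(rings) {
      rings <- lapply(rings, ring_mat)
      for (r in rings) {
        if (nrow(r) < 4 || any(r[1, ] != r[nrow(r), ]))
          stop("invalid polygon ring in feature '", nm,
               "': must be closed with >= 4 points")
      }
      polys[[length(polys) + 1]] <<- rings
      nms[length(nms) + 1] <<- nm
    }
    if (geom$type == "Polygon") {
      add(geom$coordinates)
    } else if (geom$type == "MultiPolygon") {
      for (part in geom$coordinates) add(part)
    } else {
      stop("unsupported geometry type: ", geom$type)
    }
  }
  names(polys) <- make.unique(nms)
  structure(polys, class = "polygon_set")
}

#' Write polygons to GeoJSON
#'
#' @param polys A `"polygon_set"` (see [read_polygons()]) or a single polygon
#'   (list of ring matrices).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polys, path) {
  if (!inherits(polys, "polygon_set")) polys <- as_polygon_set(polys)
  feat <- function(nm, rings) {
    coords <- lapply(rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = coords))
  }
  fc <- list(type = "FeatureCollection",
             features = unname(Map(feat, names(polys), polys)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Coerce to a polygon set
#'
#' Accepts a single ring matrix, a single polygon (list of rings), or a list
#' of polygons, and returns a `"polygon_set"`.
#' @param x Polygon-ish object.
#' @param names Optional names.
#' @export
as_polygon_set <- function(x, names = NULL) {
  if (inherits(x, "polygon_set")) return(x)
  if (is.matrix(x)) x <- list(list(x))
  else if (is.list(x) && length(x) && is.matrix(x[[1]])) x <- list(x)
  if (is.null(names)) names <- names(x) %||% paste0("poly", seq_along(x))
  x <- lapply(x, function(p) lapply(p, function(r) {
    r <- as.matrix(r)
    if (nrow(r) < 4 || any(r[1, ] != r[nrow(r), ]))
      stop("polygon rings must be closed with >= 4 points")
    r
  }))
  structure(stats::setNames(x, names), class = "polygon_set")
}

# Even-odd point-in-ring with boundary detection.
# Returns integer: 0 outside, 1 inside, 2 on boundary (within eps).
pts_in_ring <- function(px, py, ring, eps = 1e-12) {
  rx <- ring[, 1]
  ry <- ring[, 2]
  n <- length(rx)
  inside <- rep(FALSE, length(px))
  onb <- rep(FALSE, length(px))
  for (i in seq_len(n - 1)) {
    x1 <- rx[i]; y1 <- ry[i]; x2 <- rx[i + 1]; y2 <- ry[i + 1]
    # boundary: point within eps of segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      tpar <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
      d2 <- (px - (x1 + tpar * dx))^2 + (py - (y1 + tpar * dy))^2
      onb <- onb | d2 <= eps * eps
    } else {
      onb <- onb | ((px - x1)^2 + (py - y1)^2 <= eps * eps)
    }
    # even-odd ray crossing (horizontal ray to +x)
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) / (y2 - y1) * dx
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  out <- as.integer(inside)
  out[onb] <- 2L
  out
}

#' Locate points relative to polygons
#'
#' Even-odd rule with explicit boundary detection. Holes (rings after the
#' first) are handled by the even-odd parity; a point on any ring edge is
#' reported as boundary.
#'
#' @param px,py Point coordinates (same units as the polygons).
#' @param polys A `"polygon_set"`, single polygon, or ring matrix.
#' @param eps Boundary tolerance in coordinate units.
#' @return Integer vector per point: 0 = outside all polygons, 1 = strictly
#'   inside some polygon, 2 = on a boundary.
#' @export
points_in_polygon <- function(px, py, polys, eps = 1e-9) {
  polys <- as_polygon_set(polys)
  res <- rep(0L, length(px))
  for (poly in polys) {
    parity <- rep(0L, length(px))
    onb <- rep(FALSE, length(px))
    for (ring in poly) {
      r <- pts_in_ring(px, py, ring, eps)
      onb <- onb | r == 2L
      parity <- parity + as.integer(r == 1L)
    }
    inside <- parity %% 2L == 1L
    res[res == 0L & inside] <- 1L
    res[onb] <- 2L
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
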