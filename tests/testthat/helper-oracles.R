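# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: different formulations, brute force, or direct
# enumeration.

# Snyder (1987) transverse Mercator series -- independent of the package's
# Krueger-series projection.
snyder_utm <- function(lon, lat, zone) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lon0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180; lam <- lon * pi / 180
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2; C <- ep2 * cos(phi)^2; A <- (lam - lon0) * cos(phi)
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
    (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  cbind(x, y)
}

# plain ray-casting point-in-polygon (single ring, no boundary handling)
ray_cast_inside <- function(px, py, ring) {
  n <- nrow(ring)
  vapply(seq_along(px), function(k) {
    inside <- FALSE
    j <- n - 1
    for (i in seq_len(n - 1)) {
      if ((ring[i, 2] > py[k]) != (ring[j, 2] > py[k])) {
        xint <- ring[j, 1] + (py[k] - ring[j, 2]) /
          (ring[i, 2] - ring[j, 2]) * (ring[i, 1] - ring[j, 1])
        if (px[k] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, TRUE)
}

# naive O(n*w) per-window feature recomputation (no rolling shortcuts)
naive_window_features <- function(seg, half = 7, depth = NULL) {
  n <- nrow(seg)
  out <- matrix(NA_real_, n, 8, dimnames = list(NULL, c(
    "sog_avg", "sog_std", "crow_flies_km", "total_dist_km",
    "depth_avg", "depth_std", "cog_avg_abs_d", "d_cog_startend")))
  for (i in seq_len(n)) {
    a <- max(1, i - half)
    b <- min(n, i + half)
    w <- a:b
    out[i, "sog_avg"] <- mean(seg$sog[w])
    out[i, "sog_std"] <- if (length(w) > 1) sd(seg$sog[w]) else 0
    out[i, "crow_flies_km"] <- geodesic_km(seg$lat[a], seg$lon[a],
                                           seg$lat[b], seg$lon[b])
    td <- 0
    if (b > a) {
      for (j in a:(b - 1)) {
        td <- td + geodesic_km(seg$lat[j], seg$lon[j],
                               seg$lat[j + 1], seg$lon[j + 1])
      }
    }
    out[i, "total_dist_km"] <- td
    if (!is.null(depth)) {
      out[i, "depth_avg"] <- mean(depth[w])
      out[i, "depth_std"] <- if (length(w) > 1) sd(depth[w]) else 0
    }
    if (b > a) {
      turns <- abs(heading_change(seg$cog[a:(b - 1)], seg$cog[(a + 1):b]))
      out[i, "cog_avg_abs_d"] <- mean(turns)
    } else {
      out[i, "cog_avg_abs_d"] <- 0
    }
    out[i, "d_cog_startend"] <- heading_change(seg$cog[a], seg$cog[b])
  }
  out
}

# rank-based AUC, independent of pROC
rank_auc <- function(truth_fishing, score) {
  pos <- score[truth_fishing]
  neg <- score[!truth_fishing]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# cells touched by a segment, by dense sampling (grid traversal oracle)
sampled_segment_cells <- function(spec, x0, y0, x1, y1, n = 20000) {
  t <- seq(0, 1, length.out = n)
  xs <- x0 + t * (x1 - x0)
  ys <- y0 + t * (y1 - y0)
  col <- floor((xs - spec$xmin) / spec$cellsize) + 1
  row <- floor((ys - spec$ymin) / spec$cellsize) + 1
  ok <- col >= 1 & col <= spec$nx & row >= 1 & row <= spec$ny
  unique(cbind(row, col)[ok, , drop = FALSE])
}

# small shared fleet, built once per test run
tiny_fleet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_fleet(
        fleet_config(n_vessels = 8, trips_per_vessel = 3,
                     observer_coverage = 0.5, trip_hours = c(6, 9)),
        seed = 42)
    }
    cache
  }
})

# perfectly separable labeled features: fishing at constant 3 kn, transit
# at constant 10 kn, zero variance
separable_features <- function(n_trips = 10, pings_per_trip = 40) {
  rows <- lapply(seq_len(n_trips), function(i) {
    fishing <- rep(c(TRUE, FALSE), each = pings_per_trip / 2)
    data.frame(trip_id = sprintf("S%02d", i),
               sog_avg = ifelse(fishing, 3, 10), sog_std = 0,
               crow_flies_km = ifelse(fishing, 0.8, 2.5),
               total_dist_km = ifelse(fishing, 1.2, 2.5),
               fishing = fishing)
  })
  do.call(rbind, rows)
}

# labeled features with speed overlap, for permutation / OOB checks
noisy_features <- function(n = 800, p_fish = 0.5, seed = 1) {
  set.seed(seed)
  fishing <- runif(n) < p_fish
  data.frame(
    trip_id = sprintf("N%02d", sample.int(20, n, replace = TRUE)),
    sog_avg = rnorm(n, ifelse(fishing, 4.5, 9), 1),
    sog_std = abs(rnorm(n, ifelse(fishing, 0.8, 0.4), 0.2)),
    cog_avg_abs_d = abs(rnorm(n, ifelse(fishing, 20, 2), 4)),
    fishing = fishing)
}
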