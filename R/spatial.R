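# 20x20 degree grid geometry and the Matern(3/2) correlation machinery
# shared by the alpha and beta Gaussian-process fields.

EARTH_RADIUS_KM <- 6371

#' Define the global 20x20 degree grid
#'
#' Latitude edges run from -90 to 90 and longitude edges from -180 to 180 in
#' steps of `box_size_deg`, anchored at (-90, -180). With the default 20
#' degree boxes this yields 9 x 18 = 162 boxes. Box intervals are half-open
#' `[edge, edge + size)` with the top global latitude boundary closed, so
#' every valid coordinate maps to exactly one box.
#'
#' @param box_size_deg box edge length in degrees (default 20; must divide
#'   180 and 360).
#' @return object of class `grid_spec`: list with `lat_edges`, `lon_edges`,
#'   `centroids` (data.frame `box`, `lat`, `lon`), `n_lat`, `n_lon`,
#'   `box_size_deg`.
#' @export
grid_spec <- function(box_size_deg = 20) {
  if (180 %% box_size_deg != 0 || 360 %% box_size_deg != 0) {
    stopf("grid_spec: box_size_deg must divide both 180 and 360")
  }
  lat_edges <- seq(-90, 90, by = box_size_deg)
  lon_edges <- seq(-180, 180, by = box_size_deg)
  n_lat <- length(lat_edges) - 1L
  n_lon <- length(lon_edges) - 1L
  cl <- lat_edges[-length(lat_edges)] + box_size_deg / 2
  cn <- lon_edges[-length(lon_edges)] + box_size_deg / 2
  centroids <- data.frame(
    box = seq_len(n_lat * n_lon),
    lat = rep(cl, times = n_lon),
    lon = rep(cn, each = n_lat)
  )
  structure(list(lat_edges = lat_edges, lon_edges = lon_edges,
                 centroids = centroids, n_lat = n_lat, n_lon = n_lon,
                 box_size_deg = box_size_deg),
            class = "grid_spec")
}

#' Assign coordinates to grid boxes
#'
#' Vectorized point-in-box lookup under the half-open edge convention of
#' [grid_spec()]; `lat = 90` is assigned to the topmost row.
#'
#' @param lat,lon coordinates in degrees; `lon` is normalized to
#'   `[-180, 180)` internally.
#' @param grid a [grid_spec()].
#' @return integer vector of global box indices (1-based).
#' @export
assign_grid_box <- function(lat, lon, grid = grid_spec()) {
  if (any(lat < -90 | lat > 90, na.rm = TRUE)) stopf("assign_grid_box: latitude out of [-90, 90]")
  lon <- normalize_lon(lon)
  sz <- grid$box_size_deg
  i_lat <- pmin(floor((lat + 90) / sz), grid$n_lat - 1L)   # closed top boundary
  i_lon <- floor((lon + 180) / sz)
  as.integer(i_lon * grid$n_lat + i_lat + 1L)
}

#' Great-circle distance between points, in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km; symmetric, zero iff
#' the points coincide, and safe under longitude wraparound.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distances in km.
#' @export
centroid_distance_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

chordal_distance_km <- function(lat1, lon1, lat2, lon2) {
  gc <- centroid_distance_km(lat1, lon1, lat2, lon2)
  2 * EARTH_RADIUS_KM * sin(gc / (2 * EARTH_RADIUS_KM))
}

#' Matern correlation with smoothness 3/2
#'
#' `(1 + sqrt(3) * phi * d) * exp(-sqrt(3) * phi * d)`: the nu = 3/2 Matern
#' correlation scaled so that `phi` is an inverse correlation length (per
#' km). Equals 1 at d = 0, strictly decreasing, and tends to 0 as d grows.
#'
#' @param d_km distances in km, `>= 0` (vectorized).
#' @param phi inverse spatial range, per km, `> 0`.
#' @return correlations in `(0, 1]`.
#' @export
matern32 <- function(d_km, phi) {
  if (any(d_km < 0, na.rm = TRUE)) stopf("matern32: negative distance")
  if (!is_scalar_num(phi) || phi <= 0) stopf("matern32: phi must be a positive scalar")
  x <- sqrt(3) * phi * d_km
  (1 + x) * exp(-x)
}

#' Specify the spatial correlation model
#'
#' @param phi inverse spatial range, per km (> 0).
#' @param jitter diagonal inflation added before Cholesky factorization for
#'   numerical stability (default 1e-8).
#' @param distance `"chordal"` (through-the-sphere, default) or
#'   `"great_circle"` (haversine). Chordal distance is the default because
#'   the Matern family is guaranteed positive definite on the sphere only
#'   under chordal distance; with great-circle distance the global
#'   correlation matrix acquires large negative eigenvalues at small `phi`.
#'   The two are nearly identical at sub-hemispheric separations.
#' @return object of class `correlation_model` (`nu` is fixed at 3/2).
#' @export
correlation_model <- function(phi, jitter = 1e-8,
                              distance = c("chordal", "great_circle")) {
  distance <- match.arg(distance)
  if (!is_scalar_num(phi) || phi <= 0) stopf("correlation_model: phi must be a positive scalar")
  if (jitter < 0) stopf("correlation_model: jitter must be nonnegative")
  structure(list(nu = 1.5, phi = phi, jitter = jitter, distance = distance),
            class = "correlation_model")
}

#' Build the Matern correlation matrix over box centroids
#'
#' `R[i, j] = matern32(distance(c_i, c_j), phi)`. The returned matrix is
#' symmetric with unit diagonal; `R + jitter * I` is verified positive
#' definite by Cholesky factorization (jitter is escalated up to 1e-4
#' before giving up). Coincident centroids trigger a degeneracy warning.
#'
#' @param centroids data.frame with columns `lat`, `lon` (degrees).
#' @param model a [correlation_model()].
#' @return list with `R` (correlation matrix, no jitter), `chol` (upper
#'   Cholesky factor of `R + jitter_used * I`), and `jitter_used`.
#' @export
build_correlation_matrix <- function(centroids, model) {
  k <- nrow(centroids)
  if (k < 1L) stopf("build_correlation_matrix: need at least one centroid")
  lat <- centroids$lat; lon <- centroids$lon
  D <- matrix(0, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      j <- (i + 1L):k
      d <- if (model$distance == "chordal") {
        chordal_distance_km(lat[i], lon[i], lat[j], lon[j])
      } else {
        centroid_distance_km(lat[i], lon[i], lat[j], lon[j])
      }
      D[i, j] <- d
      D[j, i] <- d
    }
    if (any(D[upper.tri(D)] == 0)) {
      warnf("build_correlation_matrix: coincident centroids give off-diagonal correlation 1 (degenerate field)")
    }
  }
  R <- matern32(D, model$phi)
  diag(R) <- 1
  jit <- model$jitter
  repeat {
    ch <- tryCatch(chol(R + diag(jit, k)), error = function(e) NULL)
    if (!is.null(ch)) break
    if (jit >= 1e-4) {
      stopf("build_correlation_matrix: Cholesky failed even at jitter %g (reciprocal condition ~ %g)",
            jit, rcond(R))
    }
    jit <- max(jit * 100, 1e-10)
  }
  list(R = R, chol = ch, jitter_used = jit)
}
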