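# Calibration targets: surface temperatures extracted from a gridded
# climatology, and the gamma-weighted 0-200 m subsurface average (Sub-T).
# The gamma weighting concentrates in the shallow subsurface where pelagic
# Thaumarchaeota (the GDGT producers) reach peak abundance.

#' Gamma-pdf depth weights for the subsurface temperature target
#'
#' Weights proportional to the gamma probability density evaluated at the
#' supplied depths, renormalized to sum to 1. Defaults shape a = 4.5 and
#' scale b = 15 m give a weighting that peaks at (a-1)*b = 52.5 m with mean
#' a*b = 67.5 m, emphasizing the 0-200 m layer of GDGT production.
#'
#' @param depth_grid strictly increasing depths in meters within `[0, 200]`.
#' @param shape_a gamma shape (unitless, > 0; default 4.5).
#' @param scale_b gamma scale in meters of depth (> 0; default 15).
#' @return object of class `depth_weighting`: list with `depth_grid`,
#'   `weights` (nonnegative, summing to 1), `shape_a`, `scale_b`.
#' @export
gamma_depth_weights <- function(depth_grid, shape_a = 4.5, scale_b = 15) {
  if (length(depth_grid) == 0L) stopf("gamma_depth_weights: empty depth grid")
  if (shape_a <= 0 || scale_b <= 0) stopf("gamma_depth_weights: shape and scale must be positive")
  if (any(depth_grid < 0 | depth_grid > 200)) stopf("gamma_depth_weights: depths must lie in [0, 200] m")
  if (is.unsorted(depth_grid, strictly = TRUE)) stopf("gamma_depth_weights: depths must be strictly increasing")
  w <- stats::dgamma(depth_grid, shape = shape_a, scale = scale_b)
  s <- sum(w)
  if (s <= 0) stopf("gamma_depth_weights: all weights are zero on this grid")
  structure(list(depth_grid = depth_grid, weights = w / s,
                 shape_a = shape_a, scale_b = scale_b),
            class = "depth_weighting")
}

#' Gamma-weighted subsurface temperature (Sub-T) from a profile
#'
#' Computes the weighted average `sum(w_i * T(z_i))` of a temperature-depth
#' profile over 0-200 m with gamma-pdf weights. Profile levels below 200 m
#' receive zero weight. At shallow sites where the water column ends above
#' 200 m, the weights are renormalized over the depths actually available
#' (a plain 0-200 m average degrades badly in shallow regions; graceful
#' truncation is the point of the weighting).
#'
#' @param depth profile depths in meters (any order; `NA` temperatures are
#'   dropped with their depths).
#' @param temp temperatures in degrees C at `depth`.
#' @param shape_a,scale_b gamma weighting parameters, see
#'   [gamma_depth_weights()].
#' @param max_depth_m integration cutoff (default 200 m).
#' @return Sub-T in degrees C, bounded by the min and max of the used
#'   profile temperatures.
#' @export
subsurface_target <- function(depth, temp, shape_a = 4.5, scale_b = 15,
                              max_depth_m = 200) {
  ok <- !is.na(depth) & !is.na(temp) & depth >= 0 & depth <= max_depth_m
  if (!any(ok)) stopf("subsurface_target: no usable profile levels in [0, %g] m", max_depth_m)
  z <- depth[ok]; t <- temp[ok]
  o <- order(z)
  z <- z[o]; t <- t[o]
  if (anyDuplicated(z)) stopf("subsurface_target: duplicate profile depths")
  w <- stats::dgamma(z, shape = shape_a, scale = scale_b)
  s <- sum(w)
  if (s <= 0) stopf("subsurface_target: zero total weight on the available profile")
  sum(w / s * t)
}

#' Construct a gridded temperature climatology
#'
#' In-memory container for a WOA-style depth-resolved grid or an
#' OISST-style surface-only grid. `values` is `lat x lon` (surface) or
#' `lat x lon x depth`; `mask` is `lat x lon`, `TRUE` where ocean (valid
#' data), `FALSE` over land.
#'
#' @param lat_axis,lon_axis strictly monotone axes in degrees.
#' @param depth_axis optional strictly increasing depths in meters.
#' @param values temperature array in degrees C.
#' @param mask optional logical `lat x lon` ocean mask; default all-ocean.
#' @return object of class `climatology_grid`.
#' @export
climatology_grid <- function(lat_axis, lon_axis, values, depth_axis = NULL,
                             mask = NULL) {
  if (is.unsorted(lat_axis, strictly = TRUE) && is.unsorted(rev(lat_axis), strictly = TRUE))
    stopf("climatology_grid: lat_axis must be strictly monotone")
  if (is.unsorted(lon_axis, strictly = TRUE) && is.unsorted(rev(lon_axis), strictly = TRUE))
    stopf("climatology_grid: lon_axis must be strictly monotone")
  dims <- c(length(lat_axis), length(lon_axis),
            if (!is.null(depth_axis)) length(depth_axis))
  if (!identical(dim(values), as.integer(dims))) {
    stopf("climatology_grid: values dims (%s) do not match axes (%s)",
          paste(dim(values), collapse = "x"), paste(dims, collapse = "x"))
  }
  if (is.null(mask)) mask <- matrix(TRUE, length(lat_axis), length(lon_axis))
  if (!is.null(depth_axis) && is.unsorted(depth_axis, strictly = TRUE))
    stopf("climatology_grid: depth_axis must be strictly increasing")
  structure(list(lat_axis = lat_axis, lon_axis = lon_axis,
                 depth_axis = depth_axis, values = values, mask = mask),
            class = "climatology_grid")
}

nearest_index <- function(axis, x) which.min(abs(axis - x))

#' Extract a temperature at a point from a climatology grid
#'
#' Nearest-unmasked-cell extraction (default) or bilinear interpolation
#' where all four surrounding nodes are unmasked. Core sites often sit next
#' to land-masked cells in 1-degree products, so the nearest method
#' spiral-searches outward up to `search_radius_cells` for an ocean cell.
#' Deterministic: among equidistant candidate cells the smallest
#' (lat-index, lon-index) wins.
#'
#' @param grid a [climatology_grid()].
#' @param lat,lon query point in degrees.
#' @param depth optional depth in meters (nearest native level is used);
#'   required for depth-resolved grids unless `depth = 0` surface wanted.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @param search_radius_cells how far (in cells, Chebyshev metric) to search
#'   for an unmasked cell (default 3).
#' @return temperature in degrees C, or `NA` with attribute `reason` when
#'   all candidate cells within the search radius are masked.
#' @export
extract_point_temperature <- function(grid, lat, lon, depth = NULL,
                                      method = c("nearest", "bilinear"),
                                      search_radius_cells = 3L) {
  method <- match.arg(method)
  lon <- normalize_lon(lon)
  nlat <- length(grid$lat_axis); nlon <- length(grid$lon_axis)
  k_depth <- if (is.null(grid$depth_axis)) NULL else nearest_index(grid$depth_axis, depth %||% 0)
  val_at <- function(i, j) {
    if (is.null(k_depth)) grid$values[i, j] else grid$values[i, j, k_depth]
  }
  i0 <- nearest_index(grid$lat_axis, lat)
  j0 <- nearest_index(grid$lon_axis, lon)

  if (method == "bilinear") {
    io <- order(grid$lat_axis); jo <- order(grid$lon_axis)
    la <- grid$lat_axis[io]; lo <- grid$lon_axis[jo]
    if (lat >= la[1] && lat <= la[nlat] && lon >= lo[1] && lon <= lo[nlon]) {
      i1 <- max(findInterval(lat, la), 1L); i2 <- min(i1 + 1L, nlat)
      j1 <- max(findInterval(lon, lo), 1L); j2 <- min(j1 + 1L, nlon)
      ii <- io[c(i1, i2)]; jj <- jo[c(j1, j2)]
      if (all(grid$mask[ii, jj])) {
        tx <- if (i2 == i1) 0 else (lat - la[i1]) / (la[i2] - la[i1])
        ty <- if (j2 == j1) 0 else (lon - lo[j1]) / (lo[j2] - lo[j1])
        v11 <- val_at(ii[1], jj[1]); v21 <- val_at(ii[2], jj[1])
        v12 <- val_at(ii[1], jj[2]); v22 <- val_at(ii[2], jj[2])
        if (!anyNA(c(v11, v21, v12, v22))) {
          return((1 - tx) * (1 - ty) * v11 + tx * (1 - ty) * v21 +
                 (1 - tx) * ty * v12 + tx * ty * v22)
        }
      }
    }
    # fall through to nearest when interpolation is not possible
  }

  for (r in 0:search_radius_cells) {
    best <- NULL; best_d2 <- Inf
    for (di in -r:r) for (dj in -r:r) {
      if (max(abs(di), abs(dj)) != r) next   # ring r only
      i <- i0 + di; j <- j0 + dj
      if (i < 1L || i > nlat || j < 1L || j > nlon) next
      if (!grid$mask[i, j]) next
      v <- val_at(i, j)
      if (is.na(v)) next
      d2 <- (grid$lat_axis[i] - lat)^2 + (grid$lon_axis[j] - lon)^2
      if (d2 < best_d2) { best <- v; best_d2 <- d2 }
    }
    if (!is.null(best)) return(best)
  }
  structure(NA_real_, reason = sprintf(
    "all cells masked within %d cells of (%.3f, %.3f)", search_radius_cells, lat, lon))
}

#' Read a climatology grid from long-format CSV
#'
#' Plain-text interchange format for gridded climatologies: columns `lat`,
#' `lon`, optional `depth`, and `temp`. Missing `temp` (empty or `NaN`)
#' marks masked (land) cells. The grid is reconstructed from the unique
#' sorted axis values; every (lat, lon[, depth]) combination must appear
#' exactly once.
#'
#' @param path CSV path.
#' @return a [climatology_grid()].
#' @export
read_climatology_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA", "NaN"))
  lat_axis <- sort(unique(df$lat)); lon_axis <- sort(unique(df$lon))
  has_depth <- "depth" %in% names(df) && !all(is.na(df$depth))
  if (has_depth) {
    depth_axis <- sort(unique(df$depth))
    arr <- array(NA_real_, c(length(lat_axis), length(lon_axis), length(depth_axis)))
    arr[cbind(match(df$lat, lat_axis), match(df$lon, lon_axis),
              match(df$depth, depth_axis))] <- df$temp
    mask <- !is.na(arr[, , 1])
    climatology_grid(lat_axis, lon_axis, arr, depth_axis, mask)
  } else {
    m <- matrix(NA_real_, length(lat_axis), length(lon_axis))
    m[cbind(match(df$lat, lat_axis), match(df$lon, lon_axis))] <- df$temp
    climatology_grid(lat_axis, lon_axis, m, mask = !is.na(m))
  }
}

#' Write a climatology grid to long-format CSV
#'
#' @param grid a [climatology_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_climatology_csv <- function(grid, path) {
  if (is.null(grid$depth_axis)) {
    df <- expand.grid(lat = grid$lat_axis, lon = grid$lon_axis,
                      KEEP.OUT.ATTRS = FALSE)
    df$temp <- as.vector(grid$values)
    df$temp[!as.vector(grid$mask)] <- NA_real_
  } else {
    df <- expand.grid(lat = grid$lat_axis, lon = grid$lon_axis,
                      depth = grid$depth_axis, KEEP.OUT.ATTRS = FALSE)
    df$temp <- as.vector(grid$values)
    df$temp[!rep(as.vector(grid$mask), times = length(grid$depth_axis))] <- NA_real_
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
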