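# Synthetic world with the exact statistical structure of the calibration
# model: GP-distributed intercept/slope fields on the 20x20 degree grid,
# core-top observations tex = alpha + beta*T + eps, a smooth idealized
# climatology with land mask, and downcore series. Defaults are the stated
# conditions of the model world: mu_alpha = 0.25, mu_beta = 0.018 per degC,
# tau = 0.03 TEX86 units (the interlaboratory uncertainty scale), and a phi
# giving correlation ~0.1 at ~10,000 km.

#' Ground-truth parameter set for synthetic experiments
#'
#' @param grid a [grid_spec()].
#' @param mu_alpha,mu_beta field means (TEX86 units; TEX86 units per degC).
#' @param sigma2_alpha,sigma2_beta GP marginal variances.
#' @param tau2 observation error variance (default 0.03^2, the
#'   interlaboratory TEX86 uncertainty squared).
#' @param phi inverse spatial range per km (default 2.2e-4: correlation
#'   ~0.1 at 10,000 km).
#' @param seed integer seed; the alpha and beta fields are drawn here.
#' @return object of class `synthetic_truth` with the scalar truth, the
#'   drawn `alpha_true` / `beta_true` fields over all grid boxes, and the
#'   seed.
#' @export
synthetic_truth <- function(grid = grid_spec(), mu_alpha = 0.25,
                            mu_beta = 0.018, sigma2_alpha = 0.03^2,
                            sigma2_beta = 0.004^2, tau2 = 0.03^2,
                            phi = 2.2e-4, seed = 1) {
  alpha_true <- simulate_parameter_fields(grid, mu_alpha, sigma2_alpha, phi,
                                          truncate_positive = FALSE, seed = seed)
  beta_true <- simulate_parameter_fields(grid, mu_beta, sigma2_beta, phi,
                                         truncate_positive = TRUE, seed = seed + 1L)
  structure(list(grid = grid, mu_alpha_true = mu_alpha, mu_beta_true = mu_beta,
                 sigma2_alpha_true = sigma2_alpha, sigma2_beta_true = sigma2_beta,
                 tau2_true = tau2, phi_true = phi,
                 alpha_true = alpha_true, beta_true = beta_true, seed = seed),
            class = "synthetic_truth")
}

#' Draw a Gaussian-process parameter field on grid-box centroids
#'
#' One draw from `N(mu 1, sigma2 R(nu = 3/2, phi))` over the centroids.
#' With `truncate_positive`, the draw is redrawn until all components are
#' positive -- conditioning on the positive orthant, an acceptable stand-in
#' for exact truncated-MVN sampling when negativity is rare under the
#' chosen hyperparameters (an error is raised after 1000 rejections).
#'
#' @param grid a [grid_spec()], or a data.frame of centroids with columns
#'   `lat`, `lon`.
#' @param mu field mean.
#' @param sigma2 marginal variance (>= 0; zero gives the constant field).
#' @param phi inverse spatial range per km.
#' @param truncate_positive redraw until all components positive.
#' @param seed integer seed.
#' @param jitter correlation-matrix jitter.
#' @return numeric vector, one value per centroid.
#' @export
simulate_parameter_fields <- function(grid, mu, sigma2, phi,
                                      truncate_positive = FALSE, seed = 1,
                                      jitter = 1e-8) {
  cents <- if (inherits(grid, "grid_spec")) grid$centroids else grid
  k <- nrow(cents)
  if (sigma2 < 0) stopf("simulate_parameter_fields: sigma2 must be nonnegative")
  if (sigma2 == 0) return(rep(mu, k))
  cm <- build_correlation_matrix(cents[, c("lat", "lon")],
                                 correlation_model(phi, jitter = jitter))
  set.seed(seed)
  for (try in seq_len(1000L)) {
    x <- mu + sqrt(sigma2) * as.vector(crossprod(cm$chol, stats::rnorm(k)))
    if (!truncate_positive || all(x > 0)) return(x)
  }
  stopf("simulate_parameter_fields: < 0.1%% acceptance under positivity truncation; lower sigma2 or raise mu")
}

#' Simulate a core-top TEX86 database
#'
#' Places sites uniformly over the unmasked ocean cells of a climatology,
#' reads off surface and gamma-weighted subsurface temperatures, and
#' generates `tex86 = alpha_box + beta_box * T + eps` with
#' `eps ~ N(0, tau2)` from the supplied truth. GDGT fractional abundances
#' consistent with each TEX86 value are synthesized so records exercise the
#' full schema. Values falling outside `[0, 1]` are clipped and counted; an
#' error is raised if more than 5% clip (the truth is then implausible).
#'
#' @param n_sites number of records.
#' @param truth a [synthetic_truth()].
#' @param climatology a depth-resolved [climatology_grid()] (e.g. from
#'   [simulate_climatology()]).
#' @param target_kind which temperature drives TEX86: `"SST"` or `"SubT"`.
#' @param seed integer seed.
#' @param lat_range optional latitude band `c(min, max)` for site placement.
#' @return a `coretop_records` data.frame with an attribute `n_clipped`.
#' @export
simulate_coretops <- function(n_sites, truth, climatology,
                              target_kind = c("SST", "SubT"), seed = 1,
                              lat_range = c(-90, 90)) {
  target_kind <- match.arg(target_kind)
  if (n_sites < 1L) stopf("simulate_coretops: n_sites must be >= 1")
  ocean <- which(climatology$mask, arr.ind = TRUE)
  ocean <- ocean[climatology$lat_axis[ocean[, 1]] >= lat_range[1] &
                 climatology$lat_axis[ocean[, 1]] <= lat_range[2], , drop = FALSE]
  if (nrow(ocean) == 0L) stopf("simulate_coretops: no ocean cells in lat_range")
  set.seed(seed)
  pick <- ocean[sample.int(nrow(ocean), n_sites, replace = TRUE), , drop = FALSE]
  # jitter within the cell so sites are not exactly on nodes
  dlat <- min(diff(sort(unique(climatology$lat_axis))))
  dlon <- min(diff(sort(unique(climatology$lon_axis))))
  lat <- pmin(90, pmax(-90, climatology$lat_axis[pick[, 1]] +
                              stats::runif(n_sites, -dlat / 2, dlat / 2)))
  lon <- normalize_lon(climatology$lon_axis[pick[, 2]] +
                       stats::runif(n_sites, -dlon / 2, dlon / 2))

  sst <- numeric(n_sites); subt <- numeric(n_sites); wdep <- numeric(n_sites)
  depths <- climatology$depth_axis
  for (i in seq_len(n_sites)) {
    prof <- climatology$values[pick[i, 1], pick[i, 2], ]
    sst[i] <- prof[1]
    subt[i] <- subsurface_target(depths, prof)
    wdep[i] <- max(depths) + 500
  }
  Tt <- if (target_kind == "SST") sst else subt

  box <- assign_grid_box(lat, lon, truth$grid)
  tex_clean <- truth$alpha_true[box] + truth$beta_true[box] * Tt +
    stats::rnorm(n_sites, 0, sqrt(truth$tau2_true))
  tex <- pmin(1, pmax(0, tex_clean))
  n_clipped <- sum(tex != tex_clean)
  if (n_clipped > 0.05 * n_sites) {
    stopf("simulate_coretops: %d/%d TEX86 values clipped to [0,1]; choose tamer truth parameters",
          n_clipped, n_sites)
  }
  if (n_clipped > 0) warnf("simulate_coretops: clipped %d TEX86 value(s) to [0,1]", n_clipped)

  # GDGT fractions exactly consistent with tex: numerator split over
  # GDGT-2/3/cren', remainder of the ring-index pool to GDGT-1; GDGT-0 and
  # crenarchaeol absorb the rest of the composition.
  pool <- 0.25
  num <- tex * pool
  f1 <- pool - num
  f2 <- num * 0.4; f3 <- num * 0.35; fcp <- num * 0.25
  f0 <- (1 - pool) * 0.55
  fc <- 1 - pool - f0

  rec <- empty_coretop(n_sites)
  rec$core_id <- sprintf("SYN-%05d", seq_len(n_sites))
  rec$core_type <- rep(c("gravity", "piston", "multicore"), length.out = n_sites)
  rec$lat <- lat; rec$lon <- lon
  rec$water_depth_m <- wdep
  rec$sample_depth_cm <- rep(0, n_sites)
  rec$tex86 <- tex
  rec$f_gdgt0 <- f0; rec$f_gdgt1 <- f1; rec$f_gdgt2 <- f2; rec$f_gdgt3 <- f3
  rec$f_cren <- fc; rec$f_cren_prime <- fcp
  rec$sst_woa_C <- sst; rec$subT_gamma_C <- subt; rec$sst_oisst_C <- sst
  rec$reference <- "synthetic"
  attr(rec, "n_clipped") <- n_clipped
  rec
}

#' Simulate an idealized gridded ocean climatology
#'
#' A smooth, latitude-dominated surface field (warm equator, cold poles)
#' with mild zonal structure, exponential decay toward a cold deep layer
#' down the depth axis, and a rectangular synthetic land mask. Adequate for
#' exercising extraction and Sub-T machinery; it does not emulate real
#' bathymetry, seasonal cycles or water-mass structure.
#'
#' @param lat_step,lon_step grid resolution in degrees (default 2).
#' @param depths standard depths in meters (default WOA-like levels 0-200).
#' @param isothermal if `TRUE`, profiles are depth-constant (so Sub-T
#'   equals SST everywhere).
#' @param with_land if `TRUE` (default) mask two idealized continents.
#' @param seed integer seed for the small random zonal phase.
#' @return a depth-resolved [climatology_grid()].
#' @export
simulate_climatology <- function(lat_step = 2, lon_step = 2,
                                 depths = c(0, 10, 20, 30, 50, 75, 100, 125, 150, 200),
                                 isothermal = FALSE, with_land = TRUE, seed = 1) {
  lat_axis <- seq(-89, 89, by = lat_step)
  lon_axis <- seq(-179, 179, by = lon_step)
  set.seed(seed)
  phase <- stats::runif(1, 0, 2 * pi)
  sst <- outer(lat_axis, lon_axis, function(la, lo) {
    -1.5 + 29.5 * cos(la * pi / 180)^2 + 0.8 * sin(lo * pi / 180 + phase)
  })
  deep <- 3.5
  arr <- array(NA_real_, c(length(lat_axis), length(lon_axis), length(depths)))
  for (k in seq_along(depths)) {
    arr[, , k] <- if (isothermal) sst else deep + (sst - deep) * exp(-depths[k] / 80)
  }
  mask <- matrix(TRUE, length(lat_axis), length(lon_axis))
  if (with_land) {
    land1 <- outer(lat_axis, lon_axis, function(la, lo) la > -35 & la < 60 & lo > -85 & lo < -35)
    land2 <- outer(lat_axis, lon_axis, function(la, lo) la > -10 & la < 55 & lo > 10 & lo < 60)
    mask[land1 | land2] <- FALSE
  }
  climatology_grid(lat_axis, lon_axis, arr, depths, mask)
}

#' Simulate a downcore TEX86 series
#'
#' `tex86(t) = alpha_box + beta_box * T(t) + eps(t)` with iid normal noise,
#' for end-to-end reconstruction tests against a known temperature history.
#'
#' @param truth a [synthetic_truth()].
#' @param box global grid-box id whose true intercept/slope are used.
#' @param ages time axis (kyr BP), length >= 2.
#' @param temp_series true temperatures at `ages`, or a function of age.
#' @param tau2 noise variance (default the truth's).
#' @param seed integer seed.
#' @return data.frame with `age`, `tex86`, `temp_true`.
#' @export
simulate_downcore <- function(truth, box, ages, temp_series,
                              tau2 = truth$tau2_true, seed = 1) {
  if (length(ages) < 2L) stopf("simulate_downcore: need >= 2 time points")
  Tt <- if (is.function(temp_series)) temp_series(ages) else temp_series
  if (length(Tt) != length(ages)) stopf("simulate_downcore: temp_series length mismatch")
  set.seed(seed)
  tex <- truth$alpha_true[box] + truth$beta_true[box] * Tt +
    stats::rnorm(length(ages), 0, sqrt(tau2))
  data.frame(age = ages, tex86 = pmin(1, pmax(0, tex)), temp_true = Tt)
}
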