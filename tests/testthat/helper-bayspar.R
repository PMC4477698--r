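# Shared fixture builders. Everything is generated in code at test time;
# no data files ship with the tests.

# minimal valid core-top records at given coordinates
make_records <- function(lat, lon, tex86, sst = NULL, subt = NULL,
                         core_id = sprintf("C%03d", seq_along(lat))) {
  n <- length(lat)
  rec <- bayspar:::empty_coretop(n)
  rec$core_id <- core_id
  rec$core_type <- "gravity"
  rec$lat <- lat; rec$lon <- lon
  rec$sample_depth_cm <- seq_len(n)  # unique keys
  rec$tex86 <- tex86
  rec$sst_woa_C <- sst %||% rep(NA_real_, n)
  rec$subT_gamma_C <- subt %||% rep(NA_real_, n)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built posterior ensemble for analytics tests
make_ensemble <- function(alpha, beta, tau2, active_boxes,
                          grid = grid_spec(), box_tex_mean = NULL,
                          box_temp_mean = NULL) {
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  colnames(alpha) <- colnames(beta) <- as.character(active_boxes)
  structure(list(
    alpha = alpha, beta = beta, tau2 = tau2,
    mu_alpha = rowMeans(alpha), mu_beta = rowMeans(beta),
    sigma2_alpha = rep(1e-4, nrow(alpha)), sigma2_beta = rep(1e-6, nrow(alpha)),
    phi = rep(2.2e-4, nrow(alpha)),
    active_boxes = active_boxes, grid = grid, target_kind = "SST",
    box_tex_mean = box_tex_mean %||% rep(0.5, length(active_boxes)),
    box_temp_mean = box_temp_mean %||% rep(15, length(active_boxes)),
    n_obs_per_box = rep(1L, length(active_boxes)),
    settings = mcmc_settings(1, 2, 1, 1), seed = 1L, priors = prior_spec(),
    convergence = NULL
  ), class = "posterior_ensemble")
}

# small synthetic calibration world shared by MCMC tests: tropical sites so
# boxes are well populated and chains stay short
small_world <- function(n_sites = 300, seed = 11, lat_range = c(-30, 30)) {
  clim <- simulate_climatology(lat_step = 4, lon_step = 4, seed = seed)
  truth <- synthetic_truth(seed = seed)
  rec <- simulate_coretops(n_sites, truth, clim, seed = seed + 1L,
                           lat_range = lat_range)
  ds <- build_calibration_dataset(rec, "SST")
  list(clim = clim, truth = truth, records = rec, dataset = ds)
}
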