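# Bayesian inversion: given a TEX86 observation, a draw of the calibration
# parameters and a normal prior on temperature, the temperature posterior is
# normal (normal likelihood in T, normal prior), with
#   precision = 1/sd0^2 + beta^2/tau2
#   mean = (mu0/sd0^2 + beta*(tex - alpha)/tau2) / precision.
# Integrating over the calibration posterior is done by iterating this over
# an ensemble of parameter draws.

#' Normal prior on past temperature
#'
#' @param mean prior mean in degrees C.
#' @param sd prior standard deviation in degrees C (> 0); the default 20 is
#'   deliberately weak.
#' @return object of class `temperature_prior`.
#' @export
temperature_prior <- function(mean, sd = 20) {
  if (!is_scalar_num(mean) || !is_scalar_num(sd) || sd <= 0)
    stopf("temperature_prior: need finite mean and positive sd")
  structure(list(mean = mean, sd = sd), class = "temperature_prior")
}

# vectorized over parameter draws; returns one temperature sample per draw
invert_draws <- function(tex86, alpha, beta, tau2, prior) {
  prec <- 1 / prior$sd^2 + beta^2 / tau2
  mu <- (prior$mean / prior$sd^2 + beta * (tex86 - alpha) / tau2) / prec
  stats::rnorm(length(alpha), mu, 1 / sqrt(prec))
}

#' Invert a single TEX86 value for temperature under one parameter draw
#'
#' Samples from the exact normal temperature posterior given the draw's
#' box-specific intercept and slope, the error variance, and a normal
#' temperature prior. As `tau2 -> 0` this collapses onto the deterministic
#' inversion `(tex86 - alpha)/beta`; as `tau2 -> Inf` it reverts to the
#' prior.
#'
#' @param tex86 TEX86 observation in `[0, 1]`.
#' @param alpha,beta,tau2 calibration parameters for the site's box (beta >
#'   0, tau2 > 0).
#' @param prior a [temperature_prior()].
#' @param n number of posterior samples (default 1).
#' @return numeric vector of temperature samples in degrees C.
#' @export
invert_single <- function(tex86, alpha, beta, tau2, prior, n = 1) {
  if (tex86 < 0 || tex86 > 1) stopf("invert_single: tex86 out of [0,1]")
  if (beta <= 0 || tau2 <= 0) stopf("invert_single: beta and tau2 must be positive")
  prec <- 1 / prior$sd^2 + beta^2 / tau2
  mu <- (prior$mean / prior$sd^2 + beta * (tex86 - alpha) / tau2) / prec
  stats::rnorm(n, mu, 1 / sqrt(prec))
}

#' Probabilistic downcore temperature reconstruction
#'
#' Applies the Bayesian inversion at every time point of a downcore TEX86
#' series, iterating over a seeded subsample of calibration-posterior draws
#' so that calibration-parameter uncertainty propagates into the
#' reconstruction. Replicate TEX86 values at the same age are averaged
#' before inversion.
#'
#' @param ages time axis (kyr BP by convention), same length as `tex86`.
#' @param tex86 downcore TEX86 values in `[0, 1]`.
#' @param lat,lon site coordinates in degrees; must fall in a box active in
#'   the ensemble (deep-time analog prediction for sites outside the
#'   calibrated domain is out of scope).
#' @param ensemble a [fit_bayspar()] / [read_posterior()] ensemble.
#' @param prior a [temperature_prior()]; default mean is the ensemble's
#'   calibration-mean temperature for the site's box with sd 20 degrees C.
#' @param n_draws posterior draws used per time point (default 1000),
#'   subsampled without replacement (all draws, in order, if fewer are
#'   available).
#' @param seed integer RNG seed.
#' @return object of class `reconstruction_ensemble`: list with `ages`
#'   (sorted increasing), `draws` (time x n_draws matrix, degrees C),
#'   `site`, `box`, `target_kind`, `prior`, `seed`.
#' @export
predict_downcore <- function(ages, tex86, lat, lon, ensemble, prior = NULL,
                             n_draws = 1000, seed = 1) {
  if (length(ages) != length(tex86)) stopf("predict_downcore: ages and tex86 length mismatch")
  if (any(is.na(tex86)) || any(tex86 < 0 | tex86 > 1)) stopf("predict_downcore: tex86 values must lie in [0,1]")
  box <- assign_grid_box(lat, lon, ensemble$grid)
  j <- match(box, ensemble$active_boxes)
  if (is.na(j)) {
    stopf("predict_downcore: site (%.2f, %.2f) falls in grid box %d, which has no calibration data in this ensemble",
          lat, lon, box)
  }
  # average replicates at identical ages, then sort by age
  u_ages <- sort(unique(ages))
  tex_u <- vapply(u_ages, function(a) mean(tex86[ages == a]), numeric(1))

  if (is.null(prior)) prior <- temperature_prior(ensemble$box_temp_mean[j], 20)

  n_avail <- length(ensemble$tau2)
  set.seed(seed)
  sel <- if (n_draws < n_avail) sample.int(n_avail, n_draws) else seq_len(n_avail)
  a <- ensemble$alpha[sel, j]; b <- ensemble$beta[sel, j]; t2 <- ensemble$tau2[sel]

  draws <- matrix(NA_real_, length(u_ages), length(sel))
  for (i in seq_along(u_ages)) {
    draws[i, ] <- invert_draws(tex_u[i], a, b, t2, prior)
  }
  structure(list(ages = u_ages, draws = draws, site = c(lat = lat, lon = lon),
                 box = box, target_kind = ensemble$target_kind, prior = prior,
                 seed = seed),
            class = "reconstruction_ensemble")
}

#' @export
print.reconstruction_ensemble <- function(x, ...) {
  cat(sprintf("reconstruction_ensemble: %d time points x %d draws, box %d (%s)\n",
              nrow(x$draws), ncol(x$draws), x$box, x$target_kind))
  invisible(x)
}

#' Summarize a reconstruction ensemble
#'
#' @param object a [predict_downcore()] result.
#' @param probs quantiles to report (default 5th, 50th, 95th percentiles).
#' @param ... unused.
#' @return data.frame with `age`, `mean`, and one column per quantile.
#' @export
summary.reconstruction_ensemble <- function(object, probs = c(0.05, 0.5, 0.95), ...) {
  qs <- t(apply(object$draws, 1, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(age = object$ages, mean = rowMeans(object$draws), qs)
  names(out)[-(1:2)] <- paste0("q", probs * 100)
  out
}

#' Probability that each age bin contains the warmest conditions
#'
#' For every ensemble member, finds the warmest time point (argmax over the
#' member's temperature series; exact ties, possible only for degenerate
#' inputs, go to the earliest age) and accumulates the hits into age bins.
#' Bins are left-closed, right-open, anchored at the youngest age. Returned
#' per-bin frequencies sum to 1.
#'
#' @param recon a [predict_downcore()] result (or any list with `ages` and
#'   a time x draws matrix `draws`).
#' @param bin_width bin width in the units of `ages` (default 0.5, i.e. 500
#'   years for kyr BP axes).
#' @return data.frame with `bin_start`, `bin_end`, `probability`.
#' @export
warmest_interval_probability <- function(recon, bin_width = 0.5) {
  ages <- recon$ages; draws <- recon$draws
  if (length(ages) < 2L) stopf("warmest_interval_probability: need >= 2 time points")
  # argmax per member; max.col ties.method first row index = earliest age
  # (ages are sorted increasing)
  win <- max.col(t(draws), ties.method = "first")
  age_win <- ages[win]
  a0 <- min(ages)
  bin <- floor((age_win - a0) / bin_width)
  nb <- floor((max(ages) - a0) / bin_width) + 1L
  counts <- tabulate(bin + 1L, nbins = nb)
  data.frame(bin_start = a0 + bin_width * (seq_len(nb) - 1L),
             bin_end = a0 + bin_width * seq_len(nb),
             probability = counts / length(win))
}

#' Member-wise temperature difference between two age windows
#'
#' Per ensemble member, the mean temperature over `window_a` minus the mean
#' over `window_b` (windows are closed intervals on the age axis). The
#' member-wise differences form the posterior of the epoch contrast, e.g.
#' LGM minus Late Holocene cooling.
#'
#' @param recon a [predict_downcore()] result.
#' @param window_a,window_b length-2 numeric age ranges `c(min, max)`.
#' @param probs percentiles to report (default 5, 50, 95).
#' @return list with `differences` (one value per member) and `percentiles`
#'   (named vector).
#' @export
epoch_difference <- function(recon, window_a, window_b,
                             probs = c(0.05, 0.5, 0.95)) {
  in_a <- recon$ages >= min(window_a) & recon$ages <= max(window_a)
  in_b <- recon$ages >= min(window_b) & recon$ages <= max(window_b)
  if (!any(in_a)) stopf("epoch_difference: window_a contains no time points")
  if (!any(in_b)) stopf("epoch_difference: window_b contains no time points")
  d <- colMeans(recon$draws[in_a, , drop = FALSE]) -
       colMeans(recon$draws[in_b, , drop = FALSE])
  pct <- stats::quantile(d, probs = probs, names = FALSE)
  names(pct) <- paste0("p", probs * 100)
  list(differences = d, percentiles = pct)
}

#' Write a reconstruction ensemble to CSV
#'
#' Writes `<prefix>_draws.csv` (wide: age plus one column per ensemble
#' member), `<prefix>_summary.csv` (age, mean, 5th/50th/95th percentiles)
#' and `<prefix>.json` with provenance (site, box, prior, seed).
#'
#' @param recon a [predict_downcore()] result.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_reconstruction <- function(recon, prefix) {
  dr <- as.data.frame(recon$draws)
  names(dr) <- paste0("draw_", seq_along(dr))
  utils::write.csv(cbind(age = recon$ages, dr), paste0(prefix, "_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(summary(recon), paste0(prefix, "_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(site = as.list(recon$site), box = recon$box,
                            target_kind = recon$target_kind,
                            prior = unclass(recon$prior), seed = recon$seed),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
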