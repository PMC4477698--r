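# Hierarchical model:
#   P = M alpha + M C beta + eps,   eps ~ N(0, tau2 I)
#   alpha ~ N(mu_alpha 1, sigma2_alpha R(nu, phi))
#   beta  ~ N_[0,inf)(mu_beta 1, sigma2_beta R(nu, phi))
# with P the TEX86 observations, C the diagonal matrix of target
# temperatures, M the site-to-box selection matrix, and R the Matern(3/2)
# correlation over active-box centroids. All scalar parameters carry proper
# weakly-informative priors; phi is either fixed or given a discrete
# log-spaced grid prior updated by exact Gibbs.

#' Prior specification for the spatially-varying calibration
#'
#' Weakly-informative defaults centered on the plausible TEX86 range
#' (intercepts around 0.3) and the known slope magnitude of roughly
#' 0.015-0.02 TEX86 units per degree C. Variances get mild inverse-gamma
#' priors (shape 2: infinite prior variance, finite mean). The inverse
#' spatial range phi defaults to a discrete grid of 20 log-spaced values
#' per km with a uniform prior, updated by exact Gibbs on the grid.
#'
#' @param mu_alpha,mu_beta normal priors, `list(mean=, sd=)`.
#' @param tau2,sigma2_alpha,sigma2_beta inverse-gamma priors,
#'   `list(shape=, scale=)` (mean = scale/(shape-1)).
#' @param phi either `list(treatment = "fixed", value = )` or
#'   `list(treatment = "grid", values = , log_prior = )` (per-km values;
#'   `log_prior` defaults to uniform).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(mu_alpha = list(mean = 0.3, sd = 0.3),
                       mu_beta = list(mean = 0.02, sd = 0.02),
                       tau2 = list(shape = 2, scale = 1e-3),
                       sigma2_alpha = list(shape = 2, scale = 5e-3),
                       sigma2_beta = list(shape = 2, scale = 2e-5),
                       phi = list(treatment = "grid",
                                  values = exp(seq(log(1e-5), log(1e-2),
                                                   length.out = 20)),
                                  log_prior = NULL)) {
  for (nm in c("mu_alpha", "mu_beta")) {
    p <- get(nm)
    if (!is_scalar_num(p$mean) || !is_scalar_num(p$sd) || p$sd <= 0)
      stopf("prior_spec: %s must have finite mean and positive sd", nm)
  }
  for (nm in c("tau2", "sigma2_alpha", "sigma2_beta")) {
    p <- get(nm)
    if (!is_scalar_num(p$shape) || !is_scalar_num(p$scale) || p$shape <= 0 || p$scale <= 0)
      stopf("prior_spec: %s must have positive shape and scale", nm)
  }
  if (!phi$treatment %in% c("fixed", "grid")) stopf("prior_spec: phi treatment must be 'fixed' or 'grid'")
  if (phi$treatment == "fixed") {
    if (!is_scalar_num(phi$value) || phi$value <= 0) stopf("prior_spec: fixed phi must be a positive scalar")
  } else {
    if (any(phi$values <= 0)) stopf("prior_spec: phi grid values must be positive")
    if (is.null(phi$log_prior)) phi$log_prior <- rep(0, length(phi$values))
    if (length(phi$log_prior) != length(phi$values)) stopf("prior_spec: phi log_prior length mismatch")
  }
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta, tau2 = tau2,
                 sigma2_alpha = sigma2_alpha, sigma2_beta = sigma2_beta,
                 phi = phi),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_chains number of independent chains (default 2).
#' @param n_iter total iterations per chain, including warmup (default 7500).
#' @param n_warmup discarded warmup iterations (default 2500).
#' @param thin keep every `thin`-th post-warmup draw (default 5).
#' @param rhat_warn split-R-hat warning threshold (default 1.05).
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2, n_iter = 7500, n_warmup = 2500,
                          thin = 5, rhat_warn = 1.05) {
  if (n_warmup >= n_iter) stopf("mcmc_settings: n_warmup must be < n_iter")
  if ((n_iter - n_warmup) %% thin != 0)
    stopf("mcmc_settings: (n_iter - n_warmup) must be divisible by thin")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), thin = as.integer(thin),
                 rhat_warn = rhat_warn),
            class = "mcmc_settings")
}

# sum x within boxes, returning a length-K vector with zeros for empty boxes
box_sum <- function(x, box_index, K) {
  out <- numeric(K)
  s <- rowsum(x, box_index)
  out[as.integer(rownames(s))] <- s
  out
}

# log N(x; mu 1, sigma2 R) using the upper Cholesky factor U of R (+jitter)
mvn_logdens_chol <- function(x, mu, sigma2, U, logdetR) {
  k <- length(x)
  z <- forwardsolve(t(U), x - mu)
  -0.5 * (k * log(2 * pi * sigma2) + logdetR + sum(z^2) / sigma2)
}

#' Fit the spatially-varying TEX86 calibration by Gibbs sampling
#'
#' Samples the joint posterior of (alpha, beta, tau2, mu_alpha, mu_beta,
#' sigma2_alpha, sigma2_beta, phi) with conjugate Gibbs updates: a joint
#' multivariate-normal draw for alpha, coordinate-wise exact truncated-normal
#' draws for beta (respecting the positivity constraint), inverse-gamma
#' draws for the variances, normal draws for the field means, and, when phi
#' has a discrete grid prior, an exact categorical Gibbs draw over the grid.
#' Deterministic given `seed`, chain count and iteration schedule.
#'
#' @param dataset a [build_calibration_dataset()] result.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param seed integer RNG seed.
#' @param jitter diagonal jitter for correlation matrices (default 1e-8).
#' @param init_overrides optional named list overriding the OLS-based
#'   initialization (elements among alpha, beta, tau2, mu_alpha, mu_beta,
#'   sigma2_alpha, sigma2_beta, phi_index).
#' @return object of class `posterior_ensemble`: per-draw matrices `alpha`,
#'   `beta` (kept draws x active boxes, columns named by global box id),
#'   vectors `tau2`, `mu_alpha`, `mu_beta`, `sigma2_alpha`, `sigma2_beta`,
#'   `phi`; plus `active_boxes`, `grid`, `target_kind`, per-box calibration
#'   means `box_tex_mean` / `box_temp_mean`, `settings`, `seed`, `priors`
#'   and a `convergence` data.frame (split-R-hat and ESS per scalar).
#' @export
fit_bayspar <- function(dataset, priors = prior_spec(), mcmc = mcmc_settings(),
                        seed = 1, jitter = 1e-8, init_overrides = list()) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  P <- dataset$P; Tt <- dataset$C_diag; bi <- dataset$box_index
  n <- length(P)
  if (n == 0L) stopf("fit_bayspar: empty dataset")
  K <- length(dataset$active_boxes)
  cents <- dataset$grid$centroids[dataset$active_boxes, c("lat", "lon")]

  phi_vals <- if (priors$phi$treatment == "fixed") priors$phi$value else priors$phi$values
  phi_logp <- if (priors$phi$treatment == "fixed") 0 else priors$phi$log_prior
  G <- length(phi_vals)
  Rcache <- vector("list", G)
  for (g in seq_len(G)) {
    cm <- build_correlation_matrix(cents, correlation_model(phi_vals[g], jitter = jitter))
    Rcache[[g]] <- list(U = cm$chol, Rinv = chol2inv(cm$chol),
                        logdetR = 2 * sum(log(diag(cm$chol))))
  }

  n_k <- tabulate(bi, K)
  sT <- box_sum(Tt, bi, K)
  sT2 <- box_sum(Tt^2, bi, K)

  # per-box OLS initialization where >= 3 data exist
  init_field <- function() {
    a0 <- rep(priors$mu_alpha$mean, K); b0 <- rep(priors$mu_beta$mean, K)
    for (k in which(n_k >= 3L)) {
      sel <- bi == k
      vT <- stats::var(Tt[sel])
      if (is.finite(vT) && vT > 0) {
        sl <- stats::cov(Tt[sel], P[sel]) / vT
        b0[k] <- max(sl, 1e-4)
        a0[k] <- mean(P[sel]) - b0[k] * mean(Tt[sel])
      }
    }
    list(alpha = a0, beta = b0)
  }

  n_kept_per_chain <- (mcmc$n_iter - mcmc$n_warmup) %/% mcmc$thin
  n_kept <- n_kept_per_chain * mcmc$n_chains
  draws <- list(
    alpha = matrix(NA_real_, n_kept, K), beta = matrix(NA_real_, n_kept, K),
    tau2 = numeric(n_kept), mu_alpha = numeric(n_kept), mu_beta = numeric(n_kept),
    sigma2_alpha = numeric(n_kept), sigma2_beta = numeric(n_kept),
    phi = numeric(n_kept)
  )

  pm <- function(p) p$scale / (p$shape - 1 + (p$shape <= 1))  # prior mean, guarded
  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(seed + chain - 1L)
    f0 <- init_field()
    alpha <- init_overrides$alpha %||% f0$alpha
    beta <- pmax(init_overrides$beta %||% f0$beta, 1e-4)
    resid0 <- P - alpha[bi] - beta[bi] * Tt
    tau2 <- init_overrides$tau2 %||% max(if (n > 1L) stats::var(resid0) else 0, 1e-6)
    mu_alpha <- init_overrides$mu_alpha %||% mean(alpha)
    mu_beta <- init_overrides$mu_beta %||% mean(beta)
    var_or_0 <- function(x) if (length(x) > 1L) stats::var(x) else 0
    sigma2_alpha <- init_overrides$sigma2_alpha %||% max(var_or_0(alpha), pm(priors$sigma2_alpha))
    sigma2_beta <- init_overrides$sigma2_beta %||% max(var_or_0(beta), pm(priors$sigma2_beta))
    g <- init_overrides$phi_index %||% ((G + 1L) %/% 2L)
    Rinv <- Rcache[[g]]$Rinv

    store <- 0L
    for (it in seq_len(mcmc$n_iter)) {
      ## alpha | . : joint MVN
      Qa <- Rinv / sigma2_alpha
      Prec <- Qa
      diag(Prec) <- diag(Prec) + n_k / tau2
      b <- mu_alpha * rowSums(Qa) + box_sum(P - beta[bi] * Tt, bi, K) / tau2
      Ua <- chol(Prec)
      m <- backsolve(Ua, forwardsolve(t(Ua), b))
      alpha <- m + backsolve(Ua, stats::rnorm(K))

      ## beta | . : coordinate-wise truncated normal (exact full conditionals)
      Qb <- Rinv / sigma2_beta
      cross <- box_sum(Tt * (P - alpha[bi]), bi, K)
      for (k in seq_len(K)) {
        qkk <- Qb[k, k]
        # conditional prior mean of beta_k given beta_{-k}
        off <- sum(Qb[k, ] * (beta - mu_beta)) - qkk * (beta[k] - mu_beta)
        m_prior <- mu_beta - off / qkk
        prec <- qkk + sT2[k] / tau2
        mean_k <- (qkk * m_prior + cross[k] / tau2) / prec
        beta[k] <- rtnorm_lower(1, mean_k, 1 / sqrt(prec), 0)
      }

      ## tau2 | .
      sse <- sum((P - alpha[bi] - beta[bi] * Tt)^2)
      tau2 <- rinvgamma(1, priors$tau2$shape + n / 2, priors$tau2$scale + sse / 2)

      ## mu_alpha, mu_beta | .
      rs_a <- rowSums(Rinv)
      sRs <- sum(rs_a)
      prec_ma <- sRs / sigma2_alpha + 1 / priors$mu_alpha$sd^2
      mean_ma <- (sum(rs_a * alpha) / sigma2_alpha +
                  priors$mu_alpha$mean / priors$mu_alpha$sd^2) / prec_ma
      mu_alpha <- stats::rnorm(1, mean_ma, 1 / sqrt(prec_ma))
      prec_mb <- sRs / sigma2_beta + 1 / priors$mu_beta$sd^2
      mean_mb <- (sum(rs_a * beta) / sigma2_beta +
                  priors$mu_beta$mean / priors$mu_beta$sd^2) / prec_mb
      mu_beta <- stats::rnorm(1, mean_mb, 1 / sqrt(prec_mb))

      ## sigma2_alpha, sigma2_beta | .
      da <- alpha - mu_alpha
      quad_a <- sum(da * (Rinv %*% da))
      sigma2_alpha <- rinvgamma(1, priors$sigma2_alpha$shape + K / 2,
                                priors$sigma2_alpha$scale + quad_a / 2)
      db <- beta - mu_beta
      quad_b <- sum(db * (Rinv %*% db))
      sigma2_beta <- rinvgamma(1, priors$sigma2_beta$shape + K / 2,
                               priors$sigma2_beta$scale + quad_b / 2)

      ## phi | . : exact categorical Gibbs over the grid
      if (G > 1L) {
        lw <- vapply(seq_len(G), function(gg) {
          cc <- Rcache[[gg]]
          mvn_logdens_chol(alpha, mu_alpha, sigma2_alpha, cc$U, cc$logdetR) +
            mvn_logdens_chol(beta, mu_beta, sigma2_beta, cc$U, cc$logdetR) +
            phi_logp[gg]
        }, numeric(1))
        lw <- lw - max(lw)
        g <- sample.int(G, 1L, prob = exp(lw))
        Rinv <- Rcache[[g]]$Rinv
      }

      if (!all(is.finite(c(alpha, beta, tau2, mu_alpha, mu_beta,
                           sigma2_alpha, sigma2_beta)))) {
        stopf("fit_bayspar: non-finite state at chain %d iteration %d (tau2=%g, sigma2_alpha=%g, sigma2_beta=%g)",
              chain, it, tau2, sigma2_alpha, sigma2_beta)
      }

      if (it > mcmc$n_warmup && (it - mcmc$n_warmup) %% mcmc$thin == 0L) {
        store <- store + 1L
        idx <- (chain - 1L) * n_kept_per_chain + store
        draws$alpha[idx, ] <- alpha
        draws$beta[idx, ] <- beta
        draws$tau2[idx] <- tau2
        draws$mu_alpha[idx] <- mu_alpha
        draws$mu_beta[idx] <- mu_beta
        draws$sigma2_alpha[idx] <- sigma2_alpha
        draws$sigma2_beta[idx] <- sigma2_beta
        draws$phi[idx] <- phi_vals[g]
      }
    }
  }

  colnames(draws$alpha) <- colnames(draws$beta) <- as.character(dataset$active_boxes)

  scalars <- c("tau2", "mu_alpha", "mu_beta", "sigma2_alpha", "sigma2_beta", "phi")
  conv <- data.frame(parameter = scalars, rhat = NA_real_, ess = NA_real_)
  for (i in seq_along(scalars)) {
    x <- draws[[scalars[i]]]
    mat <- matrix(x, ncol = mcmc$n_chains)
    conv$rhat[i] <- split_rhat(mat)
    conv$ess[i] <- ess_basic(x)
  }
  bad <- !is.na(conv$rhat) & conv$rhat > mcmc$rhat_warn
  if (any(bad)) {
    warnf("fit_bayspar: split-R-hat above %.2f for: %s",
          mcmc$rhat_warn, paste(sprintf("%s (%.3f)", conv$parameter[bad], conv$rhat[bad]),
                                collapse = ", "))
  }

  structure(list(
    alpha = draws$alpha, beta = draws$beta, tau2 = draws$tau2,
    mu_alpha = draws$mu_alpha, mu_beta = draws$mu_beta,
    sigma2_alpha = draws$sigma2_alpha, sigma2_beta = draws$sigma2_beta,
    phi = draws$phi,
    active_boxes = dataset$active_boxes, grid = dataset$grid,
    target_kind = dataset$target_kind,
    box_tex_mean = as.vector(box_sum(P, bi, K) / pmax(n_k, 1L)),
    box_temp_mean = as.vector(box_sum(Tt, bi, K) / pmax(n_k, 1L)),
    n_obs_per_box = n_k,
    settings = mcmc, seed = seed, priors = priors, convergence = conv
  ), class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("posterior_ensemble: %d kept draws (%d chains), %d active boxes, target %s\n",
              length(x$tau2), x$settings$n_chains, length(x$active_boxes), x$target_kind))
  cat(sprintf("  posterior means: mu_alpha=%.4f mu_beta=%.5f tau=%.4f\n",
              mean(x$mu_alpha), mean(x$mu_beta), mean(sqrt(x$tau2))))
  invisible(x)
}

#' 1-sigma temperature prediction uncertainty for a grid box
#'
#' Standard deviation of the temperature posterior implied by the ensemble
#' for a TEX86 observation at the box's calibration mean (or a supplied
#' value), under a diffuse temperature prior. Per draw the inverse-model
#' posterior is normal with mean `(tex - alpha)/beta` and variance
#' `tau2/beta^2`; the reported uncertainty is the SD of the equal-weight
#' mixture over draws. Boxes with smaller slopes beta carry larger
#' uncertainties.
#'
#' @param ensemble a [fit_bayspar()] result.
#' @param box global grid-box id (must be active in the ensemble).
#' @param tex86 TEX86 value at which to evaluate; default the box's
#'   calibration-data mean.
#' @return 1-sigma uncertainty in degrees C.
#' @export
posterior_prediction_uncertainty <- function(ensemble, box, tex86 = NULL) {
  j <- match(box, ensemble$active_boxes)
  if (is.na(j)) stopf("posterior_prediction_uncertainty: box %s is not active in this ensemble", box)
  tex <- tex86 %||% ensemble$box_tex_mean[j]
  a <- ensemble$alpha[, j]; b <- ensemble$beta[, j]; t2 <- ensemble$tau2
  mu <- (tex - a) / b
  v <- t2 / b^2
  sqrt(mean(v) + mean(mu^2) - mean(mu)^2)
}

#' Summarize a spatial parameter field from the posterior
#'
#' Per-box posterior median and central credible interval for alpha or
#' beta, plus the global relative range of the medians,
#' `(max - min) / mean`, the statistic behind "beta varies by 30%"-style
#' summaries.
#'
#' @param ensemble a [fit_bayspar()] result.
#' @param which `"alpha"` or `"beta"`.
#' @param level central credible-interval level (default 0.9).
#' @return list with `summary` (data.frame: box, median, lower, upper) and
#'   `relative_range`.
#' @export
summarize_field <- function(ensemble, which = c("alpha", "beta"), level = 0.9) {
  which <- match.arg(which)
  m <- ensemble[[which]]
  qs <- apply(m, 2, stats::quantile, probs = c((1 - level) / 2, 0.5, (1 + level) / 2),
              names = FALSE)
  med <- qs[2, ]
  out <- data.frame(box = ensemble$active_boxes, median = med,
                    lower = qs[1, ], upper = qs[3, ])
  rel <- if (mean(med) == 0) NA_real_ else (max(med) - min(med)) / mean(med)
  list(summary = out, relative_range = rel)
}

#' Persist a posterior ensemble to CSV + JSON
#'
#' Writes `<prefix>.csv` with one row per kept draw (columns
#' `alpha_<box>`, `beta_<box>`, and the scalar parameters) and
#' `<prefix>.json` with the run metadata (active boxes, grid, target,
#' settings, seed, priors, convergence, per-box calibration means) so a
#' run's provenance travels with its output.
#'
#' @param ensemble a [fit_bayspar()] result.
#' @param prefix output path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_posterior <- function(ensemble, prefix) {
  ab <- ensemble$alpha; colnames(ab) <- paste0("alpha_", colnames(ab))
  bb <- ensemble$beta; colnames(bb) <- paste0("beta_", colnames(bb))
  df <- data.frame(ab, bb, tau2 = ensemble$tau2, mu_alpha = ensemble$mu_alpha,
                   mu_beta = ensemble$mu_beta, sigma2_alpha = ensemble$sigma2_alpha,
                   sigma2_beta = ensemble$sigma2_beta, phi = ensemble$phi,
                   check.names = FALSE)
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(
    active_boxes = ensemble$active_boxes,
    box_size_deg = ensemble$grid$box_size_deg,
    target_kind = ensemble$target_kind,
    box_tex_mean = ensemble$box_tex_mean,
    box_temp_mean = ensemble$box_temp_mean,
    n_obs_per_box = ensemble$n_obs_per_box,
    settings = unclass(ensemble$settings),
    seed = ensemble$seed,
    priors = unclass(ensemble$priors),
    convergence = ensemble$convergence
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Read a posterior ensemble written by [write_posterior()]
#'
#' @param prefix path prefix used at write time.
#' @return a `posterior_ensemble` object.
#' @export
read_posterior <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  boxes <- as.integer(meta$active_boxes)
  a <- as.matrix(df[, paste0("alpha_", boxes), drop = FALSE])
  b <- as.matrix(df[, paste0("beta_", boxes), drop = FALSE])
  colnames(a) <- colnames(b) <- as.character(boxes)
  phi_prior <- meta$priors$phi
  structure(list(
    alpha = a, beta = b, tau2 = df$tau2, mu_alpha = df$mu_alpha,
    mu_beta = df$mu_beta, sigma2_alpha = df$sigma2_alpha,
    sigma2_beta = df$sigma2_beta, phi = df$phi,
    active_boxes = boxes, grid = grid_spec(meta$box_size_deg),
    target_kind = meta$target_kind,
    box_tex_mean = meta$box_tex_mean, box_temp_mean = meta$box_temp_mean,
    n_obs_per_box = meta$n_obs_per_box,
    settings = do.call(mcmc_settings, meta$settings[c("n_chains", "n_iter", "n_warmup", "thin", "rhat_warn")]),
    seed = meta$seed,
    priors = prior_spec(mu_alpha = as.list(meta$priors$mu_alpha),
                        mu_beta = as.list(meta$priors$mu_beta),
                        tau2 = as.list(meta$priors$tau2),
                        sigma2_alpha = as.list(meta$priors$sigma2_alpha),
                        sigma2_beta = as.list(meta$priors$sigma2_beta),
                        phi = as.list(phi_prior)),
    convergence = meta$convergence
  ), class = "posterior_ensemble")
}
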