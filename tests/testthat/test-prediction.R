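test_that("invert_single collapses to the deterministic inversion as tau2 -> 0", {
  set.seed(61)
  x <- invert_single(0.5, alpha = 0.1, beta = 0.02, tau2 = 1e-12,
                     prior = temperature_prior(10, 10), n = 100)
  expect_equal(mean(x), 20.0, tolerance = 1e-3)
  expect_lt(stats::sd(x), 1e-3)
})

test_that("invert_single reverts to the prior as tau2 -> Inf", {
  set.seed(62)
  pr <- temperature_prior(12, 4)
  x <- invert_single(0.5, alpha = 0.1, beta = 0.02, tau2 = 1e12, prior = pr,
                     n = 1e4)
  expect_equal(mean(x), pr$mean, tolerance = 4 * pr$sd / sqrt(1e4) / pr$sd)
  expect_equal(stats::sd(x), pr$sd, tolerance = 0.05)
})

test_that("finite-case inversion matches a dense-grid quadrature posterior", {
  cases <- list(
    list(tex = 0.45, a = 0.20, b = 0.018, t2 = 0.03^2, m0 = 10, s0 = 15),
    list(tex = 0.70, a = 0.25, b = 0.015, t2 = 0.02^2, m0 = 25, s0 = 5),
    list(tex = 0.30, a = 0.10, b = 0.022, t2 = 0.05^2, m0 = 5, s0 = 30)
  )
  for (cs in cases) {
    pr <- temperature_prior(cs$m0, cs$s0)
    set.seed(63)
    x <- invert_single(cs$tex, cs$a, cs$b, cs$t2, pr, n = 2e5)
    # quadrature oracle: likelihood x prior on a 1e4-point temperature grid
    Tg <- seq(cs$m0 - 8 * cs$s0, cs$m0 + 8 * cs$s0, length.out = 1e4)
    post <- stats::dnorm(cs$tex, cs$a + cs$b * Tg, sqrt(cs$t2)) *
      stats::dnorm(Tg, cs$m0, cs$s0)
    post <- post / sum(post)
    m_or <- sum(Tg * post)
    s_or <- sqrt(sum((Tg - m_or)^2 * post))
    expect_equal(mean(x), m_or, tolerance = 0.01 * max(1, abs(m_or)) + 4 * s_or / sqrt(2e5))
    expect_equal(stats::sd(x), s_or, tolerance = 0.01)
  }
})

test_that("inversion is monotone in tex86 and prior-insensitive in the wide limit", {
  set.seed(64)
  means <- vapply(c(0.3, 0.45, 0.6, 0.75), function(tex) {
    mean(invert_single(tex, 0.2, 0.018, 0.03^2, temperature_prior(15, 20), n = 5e3))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # prior sd -> Inf: posterior mean -> likelihood-only mean (tex - a)/b
  wide <- mean(invert_single(0.45, 0.2, 0.018, 0.03^2,
                             temperature_prior(0, 1e4), n = 1e5))
  expect_equal(wide, (0.45 - 0.2) / 0.018, tolerance = 0.05)
})

test_that("predict_downcore handles constants, replicates and inactive boxes", {
  g <- grid_spec()
  box <- assign_grid_box(5, 5, g)
  set.seed(65)
  nd <- 400
  ens <- make_ensemble(alpha = matrix(0.2 + 0.01 * stats::rnorm(nd), nd, 1),
                       beta = matrix(abs(0.018 + 0.001 * stats::rnorm(nd)), nd, 1),
                       tau2 = rep(9e-4, nd), active_boxes = box, grid = g)
  ages <- seq(0, 10, by = 1)
  recon <- predict_downcore(ages, rep(0.5, length(ages)), 5, 5, ens, seed = 9)
  s <- summary(recon)
  # constant series: identical posterior summaries up to Monte-Carlo noise
  expect_lt(max(s$q50) - min(s$q50), 0.5)
  expect_equal(dim(recon$draws), c(length(ages), nd))
  expect_true(all(is.finite(recon$draws)))
  # replicate observations at one age are averaged before inversion
  r2 <- predict_downcore(c(0, 0, 1), c(0.4, 0.6, 0.5), 5, 5, ens, seed = 9)
  expect_equal(r2$ages, c(0, 1))
  # same seed, same data: byte-identical reconstruction
  r3 <- predict_downcore(c(0, 0, 1), c(0.4, 0.6, 0.5), 5, 5, ens, seed = 9)
  expect_identical(r2$draws, r3$draws)
  # site outside the calibrated domain names the offending box
  expect_error(predict_downcore(ages, rep(0.5, 11), -85, 100, ens, seed = 1),
               "grid box")
})

test_that("warmest-interval probabilities conserve mass and respect dominance", {
  ages <- seq(0, 9, by = 1)
  # one time point strictly dominates every member
  dom <- matrix(stats::rnorm(10 * 200), 10, 200)
  dom[4, ] <- 50
  wip <- warmest_interval_probability(list(ages = ages, draws = dom), bin_width = 1)
  expect_equal(sum(wip$probability), 1)
  expect_equal(wip$probability[wip$bin_start == 3], 1)
  # exchangeable iid ensemble: each of 10 time points ~ 0.1
  set.seed(66)
  nm <- 1e5
  exch <- matrix(stats::rnorm(10 * nm), 10, nm)
  wip2 <- warmest_interval_probability(list(ages = ages, draws = exch), bin_width = 1)
  se <- sqrt(0.1 * 0.9 / nm)
  expect_true(all(abs(wip2$probability - 0.1) < 3 * se + 1e-6))
  # ties go to the earliest age (degenerate constant members)
  tie <- matrix(1, 3, 5)
  wt <- warmest_interval_probability(list(ages = c(0, 1, 2), draws = tie), bin_width = 1)
  expect_equal(wt$probability, c(1, 0, 0))
  expect_error(warmest_interval_probability(list(ages = 1, draws = matrix(1, 1, 5))),
               ">= 2 time points")
})

test_that("epoch_difference reproduces constructed shifts and hand enumeration", {
  ages <- 0:24
  base <- matrix(stats::rnorm(25 * 300, mean = 20), 25, 300)
  shifted <- base
  shifted[ages >= 19 & ages <= 23, ] <- shifted[ages >= 19 & ages <= 23, ] - 5
  # subtracting the same window yields exactly zero
  same <- epoch_difference(list(ages = ages, draws = base), c(0, 4), c(0, 4))
  expect_true(all(same$differences == 0))
  # exact -5 shift applied to window_a in every member
  d5 <- epoch_difference(list(ages = ages, draws = shifted), c(19, 23), c(0, 4))
  dbase <- epoch_difference(list(ages = ages, draws = base), c(19, 23), c(0, 4))
  expect_equal(d5$differences, dbase$differences - 5, tolerance = 1e-12)
  expect_equal(unname(d5$percentiles["p50"] - dbase$percentiles["p50"]), -5,
               tolerance = 1e-12)
  # 3-member toy ensemble: percentiles by hand (type-7 interpolation)
  toy <- matrix(c(1, 2,   # age 0
                  5, 6,   # age 1
                  9, 14), 3, 2, byrow = TRUE)
  ed <- epoch_difference(list(ages = c(0, 1, 2), draws = toy), c(2, 2), c(0, 0))
  expect_equal(sort(ed$differences), c(8, 12))
  expect_equal(unname(ed$percentiles), c(8 + 0.05 * 4, 10, 8 + 0.95 * 4))
  expect_error(epoch_difference(list(ages = c(0, 1), draws = matrix(1, 2, 3)),
                                c(5, 6), c(0, 1)), "window_a")
})

test_that("reconstructions round-trip through the CSV writer", {
  g <- grid_spec()
  box <- assign_grid_box(5, 5, g)
  ens <- make_ensemble(alpha = matrix(0.2, 50, 1), beta = matrix(0.018, 50, 1),
                       tau2 = rep(9e-4, 50), active_boxes = box, grid = g)
  recon <- predict_downcore(0:5, rep(0.5, 6), 5, 5, ens, seed = 10)
  prefix <- file.path(withr::local_tempdir(), "recon")
  write_reconstruction(recon, prefix)
  dr <- utils::read.csv(paste0(prefix, "_draws.csv"))
  expect_equal(dim(dr), c(6L, 51L))
  expect_equal(as.matrix(dr[, -1]), unname(recon$draws), tolerance = 1e-9,
               ignore_attr = TRUE)
  sm <- utils::read.csv(paste0(prefix, "_summary.csv"))
  expect_equal(sm$q50, summary(recon)$q50, tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(meta$box, box)
})
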