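#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize longitudes to [-180, 180)
#'
#' All longitudes in the package use a single convention so that grid-box
#' assignment and great-circle distances are unambiguous.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # %% can return 360 for inputs like -1e-14 short of a multiple; clamp
  out[out >= 180] <- out[out >= 180] - 360
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Draw from an inverse-gamma distribution
#'
#' Parameterized by shape `a` and scale `b` so that the density is
#' proportional to x^(-a-1) exp(-b/x) and the mean is b/(a-1) for a > 1.
#'
#' @param n number of draws.
#' @param shape shape parameter a > 0.
#' @param scale scale parameter b > 0.
#' @return numeric vector of positive draws.
#' @keywords internal
rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

#' Sample a lower-truncated normal by inverse CDF
#'
#' Exact inverse-CDF sampling in the upper tail using log-scale quantiles,
#' which remains accurate when the truncation point is many standard
#' deviations above the mean (naive `qnorm(p0 + u*(1-p0))` degrades there).
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower truncation bound; support is `[lower, Inf)`.
#' @return numeric vector of draws `>= lower`.
#' @export
rtnorm_lower <- function(n, mean = 0, sd = 1, lower = 0) {
  if (any(sd <= 0)) stopf("rtnorm_lower: sd must be positive")
  a <- (lower - mean) / sd
  # tail prob of draw = U * tail prob of truncation point, solved on log scale
  log_tail <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  u <- stats::runif(n)
  z <- stats::qnorm(log(u) + log_tail, lower.tail = FALSE, log.p = TRUE)
  pmax(mean + sd * z, lower)
}

#' Split-chain potential scale reduction factor
#'
#' Classic split-R-hat: each chain is split in half and the usual
#' between/within variance ratio is computed over the resulting segments.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return scalar R-hat (NA if fewer than 4 draws per chain or zero variance).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(segs)
  seg_means <- colMeans(segs)
  seg_vars <- apply(segs, 2, stats::var)
  W <- mean(seg_vars)
  B <- half * stats::var(seg_means)
  if (!is.finite(W) || W <= .Machine$double.eps * mean(segs)^2) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size via initial positive sequence of autocorrelations
#'
#' @param x numeric vector of draws from one chain (or concatenated chains).
#' @return estimated effective sample size.
#' @export
ess_basic <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}
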