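#' Validate GDGT fractional abundances
#'
#' Checks a set of fractional abundances of the six main isoprenoidal GDGTs
#' (GDGT-0 through GDGT-3, crenarchaeol and its regioisomer cren').
#' Each fraction must lie in `[0, 1]`; when all six are present their sum
#' must be 1 within `sum_tol`.
#'
#' @param f_gdgt0,f_gdgt1,f_gdgt2,f_gdgt3,f_cren,f_cren_prime numeric vectors
#'   of fractional abundances (unitless); `NA` marks a missing value.
#' @param sum_tol tolerance on the deviation of the six-fraction sum from 1
#'   (default 0.02).
#' @return a data.frame of class `gdgt_fractions` with the six columns.
#' @export
gdgt_fractions <- function(f_gdgt0 = NA_real_, f_gdgt1 = NA_real_,
                           f_gdgt2 = NA_real_, f_gdgt3 = NA_real_,
                           f_cren = NA_real_, f_cren_prime = NA_real_,
                           sum_tol = 0.02) {
  fr <- data.frame(f_gdgt0 = as.numeric(f_gdgt0), f_gdgt1 = as.numeric(f_gdgt1),
                   f_gdgt2 = as.numeric(f_gdgt2), f_gdgt3 = as.numeric(f_gdgt3),
                   f_cren = as.numeric(f_cren), f_cren_prime = as.numeric(f_cren_prime))
  bad <- vapply(fr, function(x) any(!is.na(x) & (x < 0 | x > 1)), logical(1))
  if (any(bad)) {
    stopf("gdgt_fractions: fractional abundances out of [0,1]: %s",
          paste(names(fr)[bad], collapse = ", "))
  }
  all6 <- stats::complete.cases(fr)
  if (any(all6)) {
    s <- rowSums(fr[all6, , drop = FALSE])
    if (any(abs(s - 1) > sum_tol)) {
      stopf("gdgt_fractions: six-fraction sums deviate from 1 by more than %g (max deviation %g)",
            sum_tol, max(abs(s - 1)))
    }
  }
  class(fr) <- c("gdgt_fractions", class(fr))
  fr
}

#' Compute the TEX86 index from GDGT fractional abundances
#'
#' TEX86 = (GDGT-2 + GDGT-3 + cren') / (GDGT-1 + GDGT-2 + GDGT-3 + cren').
#' The index is unitless, bounded in `[0, 1]`, and invariant to rescaling
#' all four abundances by a common positive factor (absolute abundances,
#' peak areas and fractions all give the same value).
#'
#' @param f_gdgt1,f_gdgt2,f_gdgt3,f_cren_prime numeric vectors of (relative
#'   or absolute) abundances of GDGT-1, GDGT-2, GDGT-3 and the crenarchaeol
#'   regioisomer. Alternatively pass a [gdgt_fractions] object as the first
#'   argument.
#' @return numeric vector of TEX86 values in `[0, 1]`.
#' @examples
#' compute_tex86(0.1, 0.1, 0.1, 0.1)  # 0.75
#' @export
compute_tex86 <- function(f_gdgt1, f_gdgt2, f_gdgt3, f_cren_prime) {
  if (inherits(f_gdgt1, "gdgt_fractions")) {
    fr <- f_gdgt1
    return(compute_tex86(fr$f_gdgt1, fr$f_gdgt2, fr$f_gdgt3, fr$f_cren_prime))
  }
  n <- max(length(f_gdgt1), length(f_gdgt2), length(f_gdgt3), length(f_cren_prime))
  f1 <- rep_len(as.numeric(f_gdgt1), n); f2 <- rep_len(as.numeric(f_gdgt2), n)
  f3 <- rep_len(as.numeric(f_gdgt3), n); fc <- rep_len(as.numeric(f_cren_prime), n)
  miss <- is.na(f1) | is.na(f2) | is.na(f3) | is.na(fc)
  if (any(!miss & (f1 < 0 | f2 < 0 | f3 < 0 | fc < 0))) {
    stopf("compute_tex86: negative abundances are invalid")
  }
  denom <- f1 + f2 + f3 + fc
  if (any(!miss & denom <= 0)) {
    stopf("compute_tex86: zero denominator (GDGT-1 + GDGT-2 + GDGT-3 + cren' = 0); index undefined")
  }
  out <- (f2 + f3 + fc) / denom
  out[miss] <- NA_real_
  out
}
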