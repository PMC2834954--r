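#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Robust locally weighted smoothing of windowed scores
#'
#' Classic robust locally weighted scatterplot smoothing (lowess) of the
#' windowed score series against its integer positions `1..n`: for each
#' position a degree-1 weighted least-squares fit over the nearest
#' `f * n` neighbours with tricube weights, followed by 3 robustness
#' iterations that down-weight large residuals with the bisquare function.
#' This is `stats::lowess()` at exact settings (`iter = 3`, `delta = 0`,
#' no interpolation shortcut).
#'
#' @param y numeric series of length at least 2.
#' @param f fraction of points used in each local fit, in `(0, 1]`.
#' @return numeric vector of smoothed values, one per input position.
#' @examples
#' lowessSmooth(c(1, 2, 3, 4, 5), f = 1) # exactly linear in, linear out
#' @importFrom stats lowess
#' @export
lowessSmooth <- function(y, f = 1 / 3) {
  if (length(y) < 2L)
    stop("lowess smoothing needs at least 2 values", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1)
    stop("smoothing fraction f must lie in (0, 1]", call. = FALSE)
  stats::lowess(seq_along(y), y, f = f, iter = 3L, delta = 0)$y
}

#' Locate peaks in a smoothed series
#'
#' An interior index `j` (`1 < j < n`) is a peak when its value is the
#' maximum over a centred window of half-width `floor(span * n / 2)`
#' (truncated at the series boundaries) *and* strictly exceeds both
#' immediate neighbours.  Among equal-valued peaks within one window only
#' the leftmost is reported.
#'
#' @param smoothed numeric series (typically lowess output).
#' @param span window fraction in `(0, 1]`.
#' @return integer vector of peak indices (possibly empty).
#' @examples
#' findPeaks(c(1, 2, 3, 2, 1), span = 1) # 3
#' @export
findPeaks <- function(smoothed, span = 1 / 3) {
  if (!is.numeric(span) || length(span) != 1L || is.na(span) ||
      span <= 0 || span > 1)
    stop("span must lie in (0, 1]", call. = FALSE)
  n <- length(smoothed)
  if (n < 3L) return(integer(0))
  h <- floor(span * n / 2)
  peaks <- integer(0)
  for (j in 2:(n - 1L)) {
    if (!(smoothed[j] > smoothed[j - 1L] && smoothed[j] > smoothed[j + 1L]))
      next
    lo <- max(1L, j - h)
    hi <- min(n, j + h)
    if (smoothed[j] < max(smoothed[lo:hi])) next
    if (length(peaks) &&
        any(j - peaks <= h & smoothed[peaks] == smoothed[j]))
      next # leftmost of equal-valued peaks in one window
    peaks <- c(peaks, j)
  }
  peaks
}

#' Peak test statistic
#'
#' The largest local maximum of the smoothed series — the maximum of the
#' smoothed values at the peak indices of [findPeaks()] — or `NA` when no
#' peak exists.
#'
#' @inheritParams findPeaks
#' @return the test statistic, or `NA_real_` if the series has no peak.
#' @export
testStatistic <- function(smoothed, span = 1 / 3) {
  pk <- findPeaks(smoothed, span)
  if (!length(pk)) NA_real_ else max(smoothed[pk])
}

#' Extreme-value p-value of the peak statistic
#'
#' Windowed scores are treated as approximately normal and, under the
#' null, as independent; the p-value of an observed peak `sHat` over
#' `nScores` windowed scores is
#' `p = (1 - P(Z < (sHat - mu) / sigma)^nScores) * p0`, clamped to
#' `[0, 1]`, where `p0` is the null probability that any peak exists.
#' When no peak was found (`sHat` is `NA`) the p-value is 1.
#'
#' @param sHat peak statistic (may be `NA_real_`); vectorized.
#' @param nScores number of windowed scores of the alignment (`>= 1`).
#' @param calib a [NullCalibration-class] supplying `mu`, `sigma`, `p0`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' peakPValue(NA_real_, 66, NullCalibration()) # 1
#' @importFrom stats pnorm
#' @export
peakPValue <- function(sHat, nScores, calib = NullCalibration()) {
  if (any(!is.finite(nScores)) || any(nScores < 1))
    stop("nScores must be >= 1", call. = FALSE)
  p <- (1 - stats::pnorm((sHat - calib@mu) / calib@sigma)^nScores) *
    calib@p0
  p <- pmin(pmax(p, 0), 1)
  p[is.na(sHat)] <- 1
  p
}

#' FDR q-values over a batch of p-values
#'
#' The rank transform `q_i = min(k * p_i / r_i, 1)` over a batch of `k`
#' tests, where `r_i` is the rank of `p_i` (smallest ranked 1; ties broken
#' by input order with consecutive ranks).  The literal formula is applied
#' with no monotonicity enforcement.
#'
#' @param p numeric p-values in `[0, 1]`, length at least 1.
#' @return q-values in `[0, 1]`, same order as the input.
#' @examples
#' qValues(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
qValues <- function(p) {
  if (!length(p))
    stop("q-value adjustment needs at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  r <- rank(p, ties.method = "first")
  pmin(length(p) * p / r, 1)
}
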