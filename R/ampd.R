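#' Automatic multiscale-based peak detection (AMPD)
#'
#' Finds the significant extrema of a quasi-periodic series while ignoring
#' local jitter. The series is linearly detrended; a local-maxima scalogram
#' is built over window scales `k = 1 .. ceiling(n/2) - 1` (a point scores
#' at scale `k` when it exceeds both neighbours at distance `k`); the scale
#' `lambda` minimising the row-wise sum of non-maxima is selected; and the
#' reported peaks are the points that are scale-`k` maxima for every
#' `k <= lambda`. Minima are detected by negating the series.
#'
#' Three implementation details: the scalogram rows used to select `lambda`
#' count interior points only; the final detection pass truncates the
#' comparison window at the series edges, so an extremum closer than
#' `lambda` frames to an edge is still reported when it dominates its
#' in-range neighbourhood — except within `lambda / 4` frames of either
#' edge, where a one-sided window no longer supports a credible extremum;
#' and comparisons use a relative tolerance of `1e-8` of the detrended
#' range, so constant (or linear) series return no extrema.
#'
#' @param x Numeric series, length >= 8.
#' @param polarity `"maxima"` or `"minima"`.
#' @return Strictly increasing integer positions (1-based) of the detected
#'   extrema; `integer(0)` when none qualify.
#' @examples
#' x <- sin(2 * pi * 5 * (0:499) / 500)
#' ampd_extrema(x, "maxima")
#' @references Scholkmann, F., Boss, J., Wolf, M. (2012). An efficient
#'   algorithm for automatic peak detection in noisy periodic and
#'   quasi-periodic signals. Algorithms 5(4), 588-603.
#' @export
ampd_extrema <- function(x, polarity = c("maxima", "minima")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(x) || length(x) < 8) {
    abort("`x` must be a numeric series of length >= 8",
          class = "frailmotion_validation_error")
  }
  if (anyNA(x)) {
    abort("`x` must not contain missing values",
          class = "frailmotion_validation_error")
  }
  if (polarity == "minima") x <- -x
  n <- length(x)
  xd <- stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  rng <- diff(range(xd))
  # constant or linear input leaves only float dust after detrending
  if (rng <= 1e-10 * max(1, max(abs(x)))) return(integer(0))
  tol <- 1e-8 * rng

  L <- ceiling(n / 2) - 1
  n_interior_max <- integer(L)
  for (k in seq_len(L)) {
    if (n - 2 * k < 1) break
    i <- (k + 1):(n - k)
    n_interior_max[k] <- sum(xd[i] > xd[i - k] + tol & xd[i] > xd[i + k] + tol)
  }
  lambda <- which.max(n_interior_max)

  keep <- rep(TRUE, n)
  for (k in seq_len(lambda)) {
    left <- c(rep(TRUE, k), xd[(k + 1):n] > xd[1:(n - k)] + tol)
    right <- c(xd[1:(n - k)] > xd[(k + 1):n] + tol, rep(TRUE, k))
    keep <- keep & left & right
    if (!any(keep)) break
  }
  # an extremum hugging the series edge dominates only a one-sided,
  # truncated window; demand a quarter of the dominant scale of margin
  margin <- ceiling(lambda / 4)
  idx <- which(keep)
  idx[idx > margin & idx <= n - margin]
}
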