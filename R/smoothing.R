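#' Gaussian moving-average smoothing
#'
#' Depth-camera joint trajectories carry frame-to-frame jitter that creates
#' many spurious local extrema; a normalized Gaussian moving average removes
#' them while following the global oscillation of the movement. Output
#' length equals input length; at the series edges the kernel is
#' renormalized over its in-range support, so constants are preserved
#' everywhere.
#'
#' @param x Numeric series.
#' @param window Odd kernel width in frames, `1 <= window <= length(x)`.
#' @param sigma Kernel standard deviation in frames (> 0).
#' @return Smoothed numeric series of the same length.
#' @examples
#' gaussian_smooth(c(0, 0, 1, 0, 0), window = 5, sigma = 1)
#' @export
gaussian_smooth <- function(x, window, sigma = window / 5) {
  n <- length(x)
  if (length(window) != 1 || window %% 2 != 1 || window < 1 || window > n) {
    abort("`window` must be an odd integer between 1 and length(x)",
          class = "frailmotion_validation_error")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be > 0", class = "frailmotion_validation_error")
  }
  h <- (window - 1) / 2
  w <- dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  if (h == 0) return(x)
  xp <- c(rep(0, h), x, rep(0, h))
  op <- c(rep(0, h), rep(1, n), rep(0, h))
  num <- stats::convolve(xp, w, type = "filter")
  den <- stats::convolve(op, w, type = "filter")
  num / den
}

# Default kernel: 0.25 s of frames, forced odd. Suppresses sensor jitter
# while leaving movement-scale extrema (periods ~1 s and longer) intact.
default_smooth_window <- function(fps, n = Inf) {
  w <- max(3L, round(0.25 * fps))
  if (w %% 2 == 0) w <- w + 1L
  as.integer(min(w, if (n %% 2 == 0) n - 1 else n))
}

#' Smooth every joint trajectory of a recording
#'
#' Applies [gaussian_smooth()] to each of the 75 coordinate series
#' (25 joints x 3 axes). Defaults: `window` covers 0.25 s at the
#' recording's frame rate (forced odd), `sigma = window / 5`.
#'
#' @param recording An `exercise_recording`.
#' @param window,sigma Kernel parameters; `NULL` uses the defaults above.
#' @return The smoothed `exercise_recording`.
#' @export
smooth_recording <- function(recording, window = NULL, sigma = NULL) {
  arr <- recording_array(recording)
  nf <- dim(arr$coords)[1]
  window <- window %||% default_smooth_window(frame_rate(recording), nf)
  sigma <- sigma %||% (window / 5)
  for (j in seq_len(25L)) {
    for (ax in 1:3) {
      arr$coords[, j, ax] <- gaussian_smooth(arr$coords[, j, ax],
                                             window = window, sigma = sigma)
    }
  }
  out <- array_recording(arr, recording)
  attr(out, "smoothed") <- list(window = window, sigma = sigma)
  out
}
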