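#' The default low-frequency fluctuation analysis band
#'
#' Correlations are analyzed in the low-frequency domain between 0.0166 Hz
#' and 0.1 Hz; baseline drifts live below the lower edge.
#'
#' @return numeric(2): c(0.0166, 0.1) Hz.
#' @export
lff_band <- function() c(0.0166, 0.1)

#' Band specification
#'
#' @param f_lo,f_hi band edges in Hz, 0 <= f_lo < f_hi.
#' @return object of class `band_spec`.
#' @export
band_spec <- function(f_lo = 0.0166, f_hi = 0.1) {
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo < 0 || f_lo >= f_hi)
    stop(sprintf("invalid band: need 0 <= f_lo < f_hi, got [%g, %g]", f_lo, f_hi))
  structure(list(f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' Zero-phase band-pass filter for voxel time series
#'
#' Isolates the low-frequency fluctuation band in two linear, zero-phase
#' steps: each voxel series is first detrended (mean and linear trend
#' removed, which kills the spectral leakage a slow ramp would otherwise
#' smear into the band), then masked in the frequency domain: Fourier bins
#' inside [f_lo, f_hi] pass with gain 1, the gain rolls off as a raised
#' cosine over a narrow transition band outside each edge, and DC is always
#' removed, so every output series has mean ~0.
#'
#' @param run a [bold_run()] (typically GLM residuals).
#' @param band a [band_spec()] or numeric(2); default the LFF band
#'   [0.0166, 0.1] Hz.
#' @param mask optional logical 3D array; only in-mask voxels are filtered
#'   (others are zeroed), which saves substantial time on large grids.
#' @param transition_hz width of the raised-cosine roll-off outside each band
#'   edge (default 0.002 Hz).
#' @return the filtered [bold_run()].
#' @export
bandpass <- function(run, band = lff_band(), mask = NULL, transition_hz = 0.002) {
  if (inherits(band, "band_spec")) band <- c(band$f_lo, band$f_hi)
  check_band(band, run$TR)
  d <- dim(run$data)
  g <- band_gain(d[4], run$TR, band, transition_hz)
  vox <- if (is.null(mask)) seq_len(prod(d[1:3])) else mask_flat(mask)
  Y <- run_matrix(run, vox)                 # T x V
  Y <- detrend_columns(Y)
  Yf <- Re(stats::mvfft(stats::mvfft(Y) * g, inverse = TRUE)) / d[4]
  out <- matrix(0, prod(d[1:3]), d[4])
  out[vox, ] <- t(Yf)
  run$data <- array(out, d)
  attr(run, "band") <- band
  attr(run, "stage") <- "bandpassed"
  run
}

# per-bin gain vector (length n_time), symmetric in +/- frequencies
band_gain <- function(n_time, TR, band, transition_hz) {
  f <- bin_freqs(n_time, TR)
  g <- numeric(n_time)
  g[f >= band[1] & f <= band[2]] <- 1
  if (transition_hz > 0) {
    lo <- f < band[1] & f > band[1] - transition_hz
    g[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / transition_hz))
    hi <- f > band[2] & f < band[2] + transition_hz
    g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / transition_hz))
  }
  g[f == 0] <- 0
  g
}

#' Apply the band-pass filter to a plain numeric series
#'
#' Same gain contract as [bandpass()], for a single time series.
#'
#' @param x numeric series.
#' @param TR sampling interval, seconds.
#' @inheritParams bandpass
#' @return filtered series.
#' @export
bandpass_series <- function(x, TR, band = lff_band(), transition_hz = 0.002) {
  if (inherits(band, "band_spec")) band <- c(band$f_lo, band$f_hi)
  check_band(band, TR)
  y <- as.numeric(detrend_columns(matrix(x, ncol = 1)))
  g <- band_gain(length(x), TR, band, transition_hz)
  Re(stats::fft(stats::fft(y) * g, inverse = TRUE)) / length(x)
}

# remove per-column mean and linear trend (least squares)
detrend_columns <- function(Y) {
  n <- nrow(Y)
  X <- cbind(1, seq_len(n) - (n + 1) / 2)
  Y - X %*% solve(crossprod(X), crossprod(X, Y))
}
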