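#' Generate a unit-variance band-limited Gaussian series
#'
#' White Gaussian noise is shaped in the frequency domain: only Fourier bins
#' whose frequency falls inside `[f_lo, f_hi]` are retained, so essentially
#' all spectral power lies inside the band.  The series is centered and scaled
#' to unit sample variance.
#'
#' @param n_time number of time steps.
#' @param TR sampling interval in seconds.
#' @param band numeric(2), c(f_lo, f_hi) in Hz; must satisfy
#'   0 <= f_lo < f_hi <= 1/(2 TR).
#' @param seed optional integer; when given, `set.seed(seed)` is called first
#'   so two calls with the same seed return identical series.
#' @return numeric vector of length `n_time` with mean 0 and sample sd 1.
#' @export
band_limited_signal <- function(n_time, TR, band = lff_band(), seed = NULL) {
  check_band(band, TR)
  if (!is.null(seed)) set.seed(seed)
  freqs <- bin_freqs(n_time, TR)
  keep <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  if (!any(keep))
    stop("no Fourier bins fall inside the requested band; increase n_time")
  w <- stats::rnorm(n_time)
  spec <- stats::fft(w)
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n_time
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band-limited draw")
  x / s
}

# frequency of each DFT bin (two-sided folded to [0, Nyquist])
bin_freqs <- function(n_time, TR) {
  k <- 0:(n_time - 1)
  pmin(k, n_time - k) / (n_time * TR)
}

check_band <- function(band, TR) {
  if (length(band) != 2 || any(!is.finite(band)))
    stop("band must be c(f_lo, f_hi) in Hz")
  nyq <- 1 / (2 * TR)
  if (band[1] < 0 || band[1] >= band[2] || band[2] > nyq + 1e-12)
    stop(sprintf("invalid band [%g, %g] Hz: need 0 <= f_lo < f_hi <= Nyquist (%g Hz)",
                 band[1], band[2], nyq))
  invisible(TRUE)
}

#' Temporal drift basis: low-order Legendre polynomials plus slow sinusoids
#'
#' Models scanner baseline drift as deterministic slow trends.  All sinusoid
#' frequencies sit strictly below `f_max` (default 80% of the 0.0166 Hz drift
#' bound) so planted drift power stays below the analysis band.  Columns are
#' standardized to unit sample variance; per-voxel drift is obtained by mixing
#' the basis with random coefficients.
#'
#' @param n_time,TR run length and sampling interval.
#' @param n_poly number of Legendre polynomial orders (1..n_poly).
#' @param n_sin number of sinusoid pairs.
#' @param f_max upper frequency bound for the sinusoids, Hz.
#' @return matrix n_time x (n_poly + 2 n_sin).
#' @export
drift_basis <- function(n_time, TR, n_poly = 3, n_sin = 2,
                        f_max = 0.8 * 0.0166) {
  u <- seq(-1, 1, length.out = n_time)
  cols <- list()
  leg <- list(u, (3 * u^2 - 1) / 2, (5 * u^3 - 3 * u) / 2,
              (35 * u^4 - 30 * u^2 + 3) / 8)
  for (p in seq_len(min(n_poly, 4))) cols[[length(cols) + 1]] <- leg[[p]]
  t_s <- (seq_len(n_time) - 1) * TR
  if (n_sin > 0) {
    fr <- f_max * seq_len(n_sin) / n_sin
    for (f in fr) {
      cols[[length(cols) + 1]] <- sin(2 * pi * f * t_s)
      cols[[length(cols) + 1]] <- cos(2 * pi * f * t_s)
    }
  }
  B <- do.call(cbind, cols)
  B <- sweep(B, 2, colMeans(B), "-")
  sdv <- apply(B, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(B, 2, sdv, "/")
}

#' Fraction of periodogram power inside a frequency band
#'
#' Utility used to assert the spectral contracts of generated signals.
#'
#' @param x numeric series (the mean is removed first).
#' @param TR sampling interval, seconds.
#' @param band c(f_lo, f_hi) Hz.
#' @return scalar in [0, 1].
#' @export
band_power_fraction <- function(x, TR, band) {
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  f <- bin_freqs(length(x), TR)
  keep <- f > 0
  sum(p[keep & f >= band[1] & f <= band[2]]) / sum(p[keep])
}
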