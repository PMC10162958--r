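# Spectral-synthesis noise generators. Both build a Hermitian spectrum with
# random phases and a prescribed magnitude profile, invert it, and rescale
# to an exact sample standard deviation.

.fft_noise <- function(n_samples, mag) {
  n <- n_samples
  nh <- n %/% 2
  stopifnot(length(mag) == nh)
  ph <- stats::runif(nh, 0, 2 * pi)
  full <- complex(n)
  if (n %% 2 == 0) {
    # bin nh + 1 is Nyquist and must be real
    if (nh > 1) full[2:nh] <- complex(modulus = mag[seq_len(nh - 1)],
                                      argument = ph[seq_len(nh - 1)])
    full[nh + 1] <- complex(modulus = mag[nh], argument = 0)
    if (nh > 1) full[n:(nh + 2)] <- Conj(full[2:nh])
  } else {
    full[2:(nh + 1)] <- complex(modulus = mag, argument = ph)
    full[n:(nh + 2)] <- Conj(full[2:(nh + 1)])
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

.rescale_sd <- function(x, sd_target) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0 && sd_target > 0) x * (sd_target / s) else x * 0
}

#' 1/f ("pink") background noise
#'
#' Zero-mean noise whose power spectral density falls off as
#' `1/f^alpha`, rescaled to an exact sample standard deviation. `alpha = 0`
#' reduces to white noise; EEG background activity is commonly modelled
#' with `alpha` near 1.
#'
#' @param n_samples Length of the trace (>= 2).
#' @param alpha Spectral exponent (>= 0).
#' @param sd_uv Target sample standard deviation in microvolts.
#' @param fs Sampling rate in Hz (sets the frequency axis only).
#' @param seed Optional integer for reproducibility.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, alpha = 1, sd_uv = 1, fs = 1000, seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  freqs <- seq_len(n_samples %/% 2) * fs / n_samples
  mag <- freqs^(-alpha / 2)
  maybe_with_seed(seed, function() .rescale_sd(.fft_noise(n_samples, mag), sd_uv))
}

#' Band-limited Gaussian noise
#'
#' Zero-mean noise with a flat spectrum inside `band_hz` and zero outside,
#' rescaled to an exact sample standard deviation; used for basal
#' gamma-band (30-80 Hz) activity.
#'
#' @inheritParams pink_noise
#' @param band_hz Length-2 passband in Hz.
#' @export
band_noise <- function(n_samples, band_hz = c(30, 80), sd_uv = 1, fs = 1000,
                       seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  stopifnot(length(band_hz) == 2, band_hz[1] < band_hz[2])
  n_samples <- as.integer(n_samples)
  freqs <- seq_len(n_samples %/% 2) * fs / n_samples
  mag <- as.numeric(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (!any(mag > 0)) stop("band contains no frequency bins", call. = FALSE)
  maybe_with_seed(seed, function() .rescale_sd(.fft_noise(n_samples, mag), sd_uv))
}
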