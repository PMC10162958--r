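#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial with complex Morlet wavelets (Gaussian envelope
#' holding `n_cycles` cycles at each frequency, truncated at three envelope
#' SDs, unit-energy normalized) via FFT. Output samples closer to an epoch
#' edge than the wavelet half-width are flagged and excluded from window
#' averages by the downstream metrics.
#'
#' @param epochs An `epoch_set` (see [extract_epochs()]).
#' @param freqs_hz Strictly increasing frequency grid; the maximum must be
#'   below the Nyquist frequency.
#' @param n_cycles Cycles per wavelet (>= 3; default 6). Larger values
#'   trade time resolution for frequency resolution.
#' @param decim Keep every `decim`-th output sample (default 1); reduces
#'   memory for long epochs without affecting window averages materially.
#' @return A `tf_map`: complex array `trials x freqs x times` with
#'   attributes `freqs_hz`, `times_s`, `fs`, `n_cycles`, and `edge`
#'   (freqs x times logical matrix flagging edge-contaminated samples).
#' @export
morlet_tf <- function(epochs, freqs_hz, n_cycles = 6, decim = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- attr(epochs, "fs")
  times <- attr(epochs, "times")
  if (any(diff(freqs_hz) <= 0)) stop("freqs_hz must be strictly increasing",
                                     call. = FALSE)
  if (max(freqs_hz) >= fs / 2)
    stop("frequency above Nyquist (", fs / 2, " Hz)", call. = FALSE)
  if (n_cycles < 3) stop("n_cycles must be >= 3", call. = FALSE)
  x <- unclass(epochs)
  n_trials <- nrow(x); n_samp <- ncol(x)

  wavelets <- lapply(freqs_hz, function(f) {
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3 * sigma_t * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    list(w = w / sqrt(sum(Mod(w)^2)), half = half)
  })
  halves <- vapply(wavelets, `[[`, numeric(1), "half")
  nfft <- stats::nextn(n_samp + 2 * max(halves) + 1, 2)

  # FFT of all trials once
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - n_samp, n_trials)) + 0i)

  keep <- seq(1L, n_samp, by = as.integer(decim))
  out <- array(complex(1), c(n_trials, length(freqs_hz), length(keep)))
  edge <- matrix(FALSE, length(freqs_hz), length(keep))
  for (fi in seq_along(freqs_hz)) {
    wv <- wavelets[[fi]]
    Wf <- stats::fft(c(wv$w, complex(nfft - length(wv$w))))
    y <- stats::mvfft(X * Wf, inverse = TRUE) / nfft
    # centered segment of the full convolution
    sel <- (wv$half + 1L):(wv$half + n_samp)
    out[, fi, ] <- t(y[sel[keep], , drop = FALSE])
    edge[fi, ] <- keep <= wv$half | keep > n_samp - wv$half
  }
  structure(out,
            freqs_hz = freqs_hz, times_s = times[keep], fs = fs,
            n_cycles = n_cycles, edge = edge,
            class = c("tf_map", "array"))
}

#' Construct a time-frequency map from raw coefficients
#'
#' Low-level constructor, mainly for testing metrics against analytically
#' specified coefficient arrays.
#'
#' @param coefficients Complex array `trials x freqs x times`.
#' @param freqs_hz,times_s Axis grids matching the array dimensions.
#' @param fs Sampling rate (Hz).
#' @param n_cycles Wavelet width recorded as metadata.
#' @param edge Optional logical freqs x times matrix of edge flags
#'   (default all `FALSE`).
#' @return A `tf_map`.
#' @export
tf_map <- function(coefficients, freqs_hz, times_s, fs = 1000, n_cycles = 6,
                   edge = NULL) {
  stopifnot(length(dim(coefficients)) == 3,
            dim(coefficients)[2] == length(freqs_hz),
            dim(coefficients)[3] == length(times_s))
  if (is.null(edge)) edge <- matrix(FALSE, length(freqs_hz), length(times_s))
  structure(as.array(coefficients) + 0i,
            freqs_hz = freqs_hz, times_s = times_s, fs = fs,
            n_cycles = n_cycles, edge = edge,
            class = c("tf_map", "array"))
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x)
  f <- attr(x, "freqs_hz"); tt <- attr(x, "times_s")
  cat(sprintf("<tf_map> %d trials x %d freqs (%g-%g Hz) x %d times (%g..%g s)\n",
              d[1], d[2], min(f), max(f), d[3], min(tt), max(tt)))
  invisible(x)
}
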