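#' Click-evoked potential template
#'
#' Deterministic waveform used by the simulator for the response to a
#' single click: a Gaussian n1 trough flanked by smaller positive p1/p2
#' lobes. The waveform minimum equals `-|n1_amp_uv|` exactly, at the
#' sample nearest `n1_latency_s`, and the template is zero outside its
#' bounded support `[0, support_s)`.
#'
#' @param n1_amp_uv n1 trough magnitude in microvolts (>= 0).
#' @param n1_latency_s Trough latency in seconds (> 0).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param support_s Template support in seconds (default 0.3 s, so paired
#'   clicks 0.5 s apart never overlap).
#' @return Numeric vector with a `times` attribute (seconds from click).
#' @export
erp_template <- function(n1_amp_uv, n1_latency_s = 0.04,
                         sampling_rate_hz = 1000, support_s = 0.3) {
  if (n1_latency_s <= 0) stop("n1_latency_s must be > 0", call. = FALSE)
  if (n1_amp_uv < 0) stop("n1_amp_uv must be >= 0", call. = FALSE)
  n <- round(support_s * sampling_rate_hz)
  tt <- (seq_len(n) - 1) / sampling_rate_hz
  lat <- n1_latency_s
  trough <- exp(-(tt - lat)^2 / (2 * 0.008^2))
  p1 <- 0.35 * exp(-(tt - (lat - 0.025))^2 / (2 * 0.006^2))
  p2 <- 0.45 * exp(-(tt - (lat + 0.045))^2 / (2 * 0.012^2))
  w <- p1 + p2 - trough
  m <- min(w)
  w <- if (m < 0 && n1_amp_uv > 0) w * (n1_amp_uv / abs(m)) else w * 0
  attr(w, "times") <- tt
  attr(w, "fs") <- sampling_rate_hz
  w
}

#' Simulate a continuous EEG/LFP recording for a stimulation session
#'
#' Generates a multichannel trace at `params$fs` (1 kHz by default)
#' composed of 1/f background noise, band-limited (30-80 Hz) basal gamma,
#' click-evoked potential templates (second click of a pair scaled by the
#' gating factor), and -- for steady-state sessions -- a 40 Hz sinusoid per
#' train whose phase relative to train onset is drawn from a von Mises
#' distribution with concentration `assr_kappa`, with amplitude
#' `assr_amp_uv * initial_boost` during the first 50 ms and `assr_amp_uv`
#' thereafter. For opto-flagged trials the basal-gamma amplitude within the
#' trial is multiplied by `opto_gamma_gain` and the phase concentration by
#' `opto_kappa_factor`.
#'
#' Noise components are drawn independently per channel; the evoked signal
#' (ERP templates and entrained sinusoid, including trial phases) is shared
#' across channels, as volume-conducted signal components are.
#'
#' @param protocol A `stim_protocol`.
#' @param events Its event table (optionally with opto flags set).
#' @param params A [condition_params()] object.
#' @param channels Character vector of channel labels (e.g. `c("AC",
#'   "mPFC")`).
#' @param seed Optional integer for bit-reproducible output.
#' @param pad_s Seconds of recording before the first event and after the
#'   last trial (default 3 s, enough for baseline windows and wavelet
#'   edges).
#' @return An `eeg_recording`: list with `data` (samples x channels matrix,
#'   microvolts), `fs`, `start_s`, `channels`, and a `ground_truth`
#'   attribute holding the parameters and per-trial entrainment phases.
#' @export
synth_continuous <- function(protocol, events, params = condition_params(),
                             channels = "AC", seed = NULL, pad_s = 3) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(params, "condition_params"))
  fs <- params$fs
  tail_s <- if (protocol$kind == "assr_train") protocol$train_dur_s else
    protocol$pair_gap_s + 0.5
  start_s <- -pad_s
  end_s <- max(events$onset_s) + tail_s + pad_s
  if (any(events$onset_s < start_s) ||
      any(events$onset_s + tail_s > end_s))
    stop("simulation error: event outside session span", call. = FALSE)
  n <- round((end_s - start_s) * fs)
  idx_of <- function(t) round((t - start_s) * fs) + 1L

  build <- function() {
    data <- matrix(0, n, length(channels),
                   dimnames = list(NULL, channels))
    for (j in seq_along(channels))
      data[, j] <- pink_noise(n, params$noise_alpha, params$noise_sd_uv, fs)
    gamma <- matrix(0, n, length(channels))
    for (j in seq_along(channels))
      gamma[, j] <- band_noise(n, c(30, 80), params$basal_gamma_sd_uv, fs)

    trains <- events[events$event_type == "train_start", , drop = FALSE]
    # opto trials: scale the gamma component across the whole trial block
    if (nrow(trains) && any(trains$opto) && params$opto_gamma_gain != 1) {
      for (k in which(trains$opto)) {
        i0 <- max(1L, idx_of(trains$onset_s[k] - 2.5))
        i1 <- min(n, idx_of(trains$onset_s[k] + protocol$train_dur_s + 0.5))
        gamma[i0:i1, ] <- gamma[i0:i1, ] * params$opto_gamma_gain
      }
    }
    data <- data + gamma

    sig <- numeric(n)
    tmpl <- erp_template(params$n1_amp_uv, params$n1_latency_s, fs)
    add_tmpl <- function(onset, scale) {
      i0 <- idx_of(onset)
      ii <- i0 + seq_along(tmpl) - 1L
      keep <- ii >= 1L & ii <= n
      sig[ii[keep]] <<- sig[ii[keep]] + scale * tmpl[keep]
    }
    c1 <- events$onset_s[events$event_type == "click1"]
    c2 <- events$onset_s[events$event_type == "click2"]
    for (o in c1) add_tmpl(o, 1)
    for (o in c2) add_tmpl(o, params$gating_g)

    phases <- NULL
    if (nrow(trains)) {
      f0 <- protocol$click_rate_hz
      kap <- params$assr_kappa *
        ifelse(trains$opto, params$opto_kappa_factor, 1)
      phases <- vapply(kap, function(k) rvonmises(1, k), numeric(1))
      for (k in seq_len(nrow(trains))) {
        on <- trains$onset_s[k]
        i0 <- idx_of(on)
        i1 <- idx_of(on + protocol$train_dur_s) - 1L
        ii <- i0:i1
        t_rel <- (ii - i0) / fs
        amp <- params$assr_amp_uv *
          ifelse(t_rel < 0.05, params$initial_boost, 1)
        sig[ii] <- sig[ii] + amp * sin(2 * pi * f0 * t_rel + phases[k])
      }
    }
    data <- data + sig
    structure(
      list(data = data, fs = fs, start_s = start_s, channels = channels),
      ground_truth = list(params = params, assr_phase = phases,
                          opto = if (nrow(trains)) trains$opto else NULL),
      class = "eeg_recording")
  }
  maybe_with_seed(seed, build)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %d samples @ %g Hz, t = %g..%g s\n",
              ncol(x$data), paste(x$channels, collapse = ", "), nrow(x$data),
              x$fs, x$start_s, x$start_s + nrow(x$data) / x$fs))
  invisible(x)
}
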