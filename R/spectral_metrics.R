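#' Analysis windows for steady-state responses
#'
#' The baseline (BL), initial-response (In) and maintenance-phase (MP)
#' windows, in seconds relative to train onset: BL spans the 2 s up to
#' stimulation start, In the first 50 ms of the response, MP 50-2000 ms
#' into the steady-state response.
#'
#' @param bl,initial,maintenance Length-2 windows in seconds.
#' @return A `phase_windows` list.
#' @export
phase_windows <- function(bl = c(-2, 0), initial = c(0, 0.05),
                          maintenance = c(0.05, 2)) {
  w <- list(bl = bl, initial = initial, maintenance = maintenance)
  for (x in w) stopifnot(length(x) == 2, x[1] < x[2])
  if (bl[2] > initial[1] || initial[2] > maintenance[1])
    stop("phase windows must be ordered and non-overlapping", call. = FALSE)
  structure(w, class = "phase_windows")
}

# Rectangle selector: indices of freqs in band and unflagged times in window.
.tf_rect <- function(tfmap, band_hz, window_s) {
  freqs <- attr(tfmap, "freqs_hz")
  times <- attr(tfmap, "times_s")
  fi <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  ti <- which(times >= window_s[1] & times <= window_s[2])
  if (!length(fi) || !length(ti))
    stop("empty rectangle: band/window selects no cells", call. = FALSE)
  list(fi = fi, ti = ti, edge = attr(tfmap, "edge")[fi, ti, drop = FALSE])
}

#' Inter-trial coherence
#'
#' ITC at each time-frequency point is the mean resultant length of the
#' per-trial coefficient phases, `|mean_k exp(i phi_k)|`, in `[0, 1]`:
#' 1 means perfect phase locking across trials, values near `sqrt(pi) /
#' (2 sqrt(N))` arise from fully random phases. Trials with a
#' zero-magnitude coefficient have no defined phase and are excluded at
#' that point (excluded counts are reported).
#'
#' @param tfmap A `tf_map` with at least 2 trials.
#' @return An `itc_result`: list with `itc` (freqs x times matrix),
#'   `n_trials`, `n_excluded` (freqs x times), `freqs_hz`, `times_s`,
#'   `edge`.
#' @export
itc <- function(tfmap) {
  stopifnot(inherits(tfmap, "tf_map"))
  n_trials <- dim(tfmap)[1]
  if (n_trials < 2) stop("ITC requires >= 2 trials", call. = FALSE)
  mod <- Mod(tfmap)
  unit <- unclass(tfmap)
  zero <- mod == 0
  unit[!zero] <- unit[!zero] / mod[!zero]
  unit[zero] <- NA_complex_
  n_eff <- colSums(!zero) # sums over the trial dimension
  sums <- colSums(Re(unit), na.rm = TRUE) + 1i * colSums(Im(unit), na.rm = TRUE)
  r <- matrix(0, dim(tfmap)[2], dim(tfmap)[3])
  pos <- n_eff > 0
  r[pos] <- Mod(sums[pos]) / n_eff[pos]
  structure(list(itc = r, n_trials = n_trials,
                 n_excluded = n_trials - n_eff,
                 freqs_hz = attr(tfmap, "freqs_hz"),
                 times_s = attr(tfmap, "times_s"),
                 edge = attr(tfmap, "edge")),
            class = "itc_result")
}

#' Band power over a time-frequency rectangle
#'
#' `mode = "total"` averages single-trial power `|z|^2` over trials and
#' the rectangle (induced plus evoked activity); `mode = "evoked"`
#' averages the power of the trial-mean coefficient `|mean_k z_k|^2`
#' (only phase-locked activity survives). Edge-flagged samples are
#' excluded. By Jensen's inequality evoked power never exceeds total
#' power.
#'
#' @param tfmap A `tf_map`.
#' @param band_hz Length-2 frequency band (Hz).
#' @param window_s Length-2 time window (s, relative to the event).
#' @param mode `"total"` or `"evoked"`.
#' @return Scalar power in microvolts squared (up to the unit-energy
#'   wavelet scaling, constant across comparisons).
#' @export
band_power <- function(tfmap, band_hz, window_s,
                       mode = c("total", "evoked")) {
  stopifnot(inherits(tfmap, "tf_map"))
  mode <- match.arg(mode)
  r <- .tf_rect(tfmap, band_hz, window_s)
  sub <- unclass(tfmap)[, r$fi, r$ti, drop = FALSE]
  keep <- !r$edge
  if (!any(keep))
    stop("empty rectangle: all samples edge-flagged", call. = FALSE)
  if (mode == "total") {
    pw <- colMeans(Mod(sub)^2) # over the trial dimension
  } else {
    pw <- Mod(colMeans(Re(sub)) + 1i * colMeans(Im(sub)))^2
  }
  pw <- matrix(pw, length(r$fi), length(r$ti))
  mean(pw[keep])
}

#' Basal (pre-stimulus) gamma-band power
#'
#' Total-mode 30-80 Hz power in a window that lies entirely before the
#' aligning event; the default window (-1.5 to -0.5 s) sits inside the
#' baseline period but clear of wavelet edge effects.
#'
#' @param epochs An `epoch_set` aligned to stimulus onset with >= 2 s of
#'   pre-stimulus signal.
#' @param band_hz Gamma band (default 30-80 Hz).
#' @param window_s Pre-stimulus window (default `c(-1.5, -0.5)`).
#' @param freq_step_hz Grid step of the internal wavelet decomposition.
#' @param n_cycles Wavelet width.
#' @return Scalar power (microvolts squared).
#' @export
basal_gamma <- function(epochs, band_hz = c(30, 80),
                        window_s = c(-1.5, -0.5), freq_step_hz = 2,
                        n_cycles = 6) {
  if (window_s[2] > 0)
    stop("basal window must lie entirely before the event", call. = FALSE)
  freqs <- seq(band_hz[1], band_hz[2], by = freq_step_hz)
  tf <- morlet_tf(epochs, freqs, n_cycles = n_cycles)
  band_power(tf, band_hz, window_s, mode = "total")
}

#' Steady-state 40 Hz metrics split into initial and maintenance phases
#'
#' Evoked-mode power and inter-trial coherence at the stimulation
#' frequency, averaged within the initial (0-50 ms) and maintenance
#' (50-2000 ms) windows, excluding edge-flagged samples. Total-mode power
#' is reported alongside.
#'
#' @param tfmap A `tf_map` whose grid contains `f0`.
#' @param windows A [phase_windows()] object.
#' @param f0 Stimulation frequency (default 40 Hz).
#' @return One-row data frame: `power40_in`, `power40_mp` (evoked),
#'   `power40_in_total`, `power40_mp_total`, `itc40_in`, `itc40_mp`.
#' @export
assr_metrics <- function(tfmap, windows = phase_windows(), f0 = 40) {
  stopifnot(inherits(tfmap, "tf_map"))
  freqs <- attr(tfmap, "freqs_hz")
  fi <- which(abs(freqs - f0) < 1e-9)
  if (!length(fi)) stop("f0 not on the frequency grid", call. = FALSE)
  ic <- itc(tfmap)
  times <- attr(tfmap, "times_s")
  avg_itc <- function(win) {
    ti <- which(times >= win[1] & times <= win[2])
    keep <- !attr(tfmap, "edge")[fi, ti]
    if (!any(keep)) stop("empty rectangle: all samples edge-flagged",
                         call. = FALSE)
    mean(ic$itc[fi, ti][keep])
  }
  data.frame(
    power40_in = band_power(tfmap, c(f0, f0), windows$initial, "evoked"),
    power40_mp = band_power(tfmap, c(f0, f0), windows$maintenance, "evoked"),
    power40_in_total = band_power(tfmap, c(f0, f0), windows$initial, "total"),
    power40_mp_total = band_power(tfmap, c(f0, f0), windows$maintenance,
                                  "total"),
    itc40_in = avg_itc(windows$initial),
    itc40_mp = avg_itc(windows$maintenance))
}

#' Steady-state session metrics from a continuous recording
#'
#' Convenience wrapper: epochs the recording around train onsets, runs the
#' wavelet decomposition, and returns the 40 Hz phase metrics plus basal
#' gamma power from the same epochs.
#'
#' @param recording,events Session recording and event table.
#' @param channel Channel label or index.
#' @param f0 Stimulation frequency (Hz).
#' @param freqs_hz Wavelet grid; must contain `f0` and cover the gamma
#'   band (default 30-80 Hz in 5 Hz steps).
#' @param windows A [phase_windows()] object.
#' @param trial_subset Optional logical vector over trains (e.g. opto
#'   flags) selecting which trials to analyze.
#' @param pre_s,post_s Epoch extent (defaults cover BL and the full train
#'   plus wavelet margins).
#' @return One-row data frame: [assr_metrics()] columns plus
#'   `basal_gamma_uv2` and `n_trials_used`.
#' @export
assr_session_metrics <- function(recording, events, channel = 1, f0 = 40,
                                 freqs_hz = seq(30, 80, by = 5),
                                 windows = phase_windows(),
                                 trial_subset = NULL,
                                 pre_s = 2.5, post_s = 2.3) {
  ev <- events
  if (!is.null(trial_subset)) {
    trains <- which(ev$event_type == "train_start")
    keep_ids <- ev$trial_id[trains][trial_subset]
    ev <- ev[ev$trial_id %in% keep_ids, , drop = FALSE]
  }
  ep <- extract_epochs(recording, ev, "train_start", pre_s, post_s,
                       channel = channel, baseline_window = c(-2, 0))
  tf <- morlet_tf(ep, freqs_hz)
  out <- assr_metrics(tf, windows, f0)
  out$basal_gamma_uv2 <- band_power(tf, c(30, 80), c(-1.5, -0.5), "total")
  out$n_trials_used <- n_epochs(ep)
  out
}
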