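#' Extract trial-aligned epochs from a continuous recording
#'
#' Cuts `[onset - pre_s, onset + post_s)` segments around every event of
#' the requested type. Trials whose window falls outside the recording are
#' dropped with an `"edge"` reason; trials containing any sample exceeding
#' `reject_uv` in magnitude are dropped with an `"amplitude"` reason.
#'
#' @param recording An `eeg_recording` (see [synth_continuous()]).
#' @param events Event table with `onset_s`, `event_type`, `trial_id`,
#'   `opto`.
#' @param event_type Which event type to align on (e.g. `"click1"`,
#'   `"train_start"`).
#' @param pre_s,post_s Window extent in seconds before/after the event
#'   (both >= 0).
#' @param channel Channel label or index (default first channel).
#' @param reject_uv Peak-to-zero artifact-rejection threshold in
#'   microvolts (default `Inf`, i.e. off).
#' @param baseline_window Length-2 window (seconds relative to the event)
#'   used for baseline correction downstream; must lie inside the epoch.
#' @return An `epoch_set`: trials x samples matrix with attributes
#'   `times` (seconds relative to event), `fs`, `info` (per-trial
#'   metadata), `baseline_window`, and `rejections` (named counts).
#' @export
extract_epochs <- function(recording, events, event_type, pre_s, post_s,
                           channel = 1, reject_uv = Inf,
                           baseline_window = c(-0.1, 0)) {
  stopifnot(inherits(recording, "eeg_recording"), pre_s >= 0, post_s >= 0)
  ev <- events[events$event_type == event_type, , drop = FALSE]
  if (!nrow(ev))
    stop("empty-epochs error: no events of type '", event_type, "'",
         call. = FALSE)
  fs <- recording$fs
  x <- recording$data[, channel]
  n <- length(x)
  len <- round((pre_s + post_s) * fs)
  if (len < 1) stop("empty-epochs error: zero-length window", call. = FALSE)
  times <- (seq_len(len) - 1) / fs - pre_s
  if (baseline_window[1] < -pre_s || baseline_window[2] > post_s)
    stop("baseline_window must lie inside the epoch window", call. = FALSE)

  i0 <- round((ev$onset_s - pre_s - recording$start_s) * fs) + 1L
  ok_edge <- i0 >= 1L & (i0 + len - 1L) <= n
  n_edge <- sum(!ok_edge)
  ev <- ev[ok_edge, , drop = FALSE]
  i0 <- i0[ok_edge]
  if (!nrow(ev))
    stop("empty-epochs error: all trials rejected at recording edges",
         call. = FALSE)
  m <- t(vapply(i0, function(i) x[i:(i + len - 1L)], numeric(len)))
  ok_amp <- apply(abs(m) <= reject_uv, 1, all)
  n_amp <- sum(!ok_amp)
  m <- m[ok_amp, , drop = FALSE]
  ev <- ev[ok_amp, , drop = FALSE]
  if (!nrow(m))
    stop("empty-epochs error: all trials rejected by amplitude threshold",
         call. = FALSE)
  structure(m,
            times = times, fs = fs,
            info = data.frame(trial_id = ev$trial_id, opto = ev$opto,
                              onset_s = ev$onset_s),
            baseline_window = baseline_window,
            rejections = c(edge = n_edge, amplitude = n_amp),
            class = c("epoch_set", "matrix"))
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_epochs <- function(epochs) nrow(epochs)

#' Trial-averaged evoked waveform
#'
#' Pointwise mean over trials, optionally after subtracting each trial's
#' mean over the baseline window.
#'
#' @param epochs An `epoch_set`.
#' @param baseline_correct Subtract the per-trial baseline mean first
#'   (default `TRUE`).
#' @return Numeric waveform with `times` and `fs` attributes.
#' @export
average_erp <- function(epochs, baseline_correct = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"), nrow(epochs) >= 1)
  times <- attr(epochs, "times")
  m <- unclass(epochs)
  if (baseline_correct) {
    bw <- attr(epochs, "baseline_window")
    sel <- times >= bw[1] & times < bw[2]
    if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
    m <- m - rowMeans(m[, sel, drop = FALSE])
  }
  w <- colMeans(m)
  attr(w, "times") <- times
  attr(w, "fs") <- attr(epochs, "fs")
  w
}
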