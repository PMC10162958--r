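#' Measure the n1 component on an averaged waveform
#'
#' The n1 is taken as the minimum of the averaged waveform inside the
#' search window; its amplitude is the signed value in microvolts and its
#' latency the time of that minimum (ties broken by the earliest time).
#'
#' @param avg_waveform Waveform with a `times` attribute (see
#'   [average_erp()]).
#' @param search_start_s,search_end_s Search window in seconds relative to
#'   the event (defaults 0.01-0.1 s).
#' @return List with `amplitude_uv` and `latency_s`.
#' @export
measure_n1 <- function(avg_waveform, search_start_s = 0.01,
                       search_end_s = 0.1) {
  times <- attr(avg_waveform, "times")
  if (is.null(times)) stop("waveform lacks a times attribute", call. = FALSE)
  sel <- which(times >= search_start_s & times <= search_end_s)
  if (!length(sel)) stop("empty n1 search window", call. = FALSE)
  w <- as.numeric(avg_waveform)[sel]
  i <- which.min(w) # which.min returns the earliest tie
  list(amplitude_uv = w[i], latency_s = times[sel[i]])
}

#' Sensory-gating ratio
#'
#' Ratio of the second-click to first-click n1 amplitude (signed; two
#' genuine negative troughs give a positive ratio). Values near 0 indicate
#' strong gating, values near 1 indicate none.
#'
#' @param n1_s1_uv,n1_s2_uv Signed n1 amplitudes for S1 and S2.
#' @return Numeric ratio.
#' @export
gating_ratio <- function(n1_s1_uv, n1_s2_uv) {
  if (any(n1_s1_uv == 0))
    stop("undefined-gating error: S1 amplitude is zero", call. = FALSE)
  n1_s2_uv / n1_s1_uv
}

#' Full ERP metric set for one double-click session
#'
#' Epochs the recording around both clicks of each pair, averages, and
#' measures n1 amplitude and latency per click plus the gating ratio and
#' gating difference (S1 - S2).
#'
#' @param recording An `eeg_recording` from a double-click session.
#' @param events Its event table.
#' @param channel Channel label or index.
#' @param pre_s,post_s Epoch window (defaults 0.2 s pre, 0.3 s post).
#' @param search_window n1 search window in seconds (default `c(0.01, 0.1)`).
#' @param reject_uv Artifact threshold passed to [extract_epochs()].
#' @return One-row data frame: `n1_s1_uv`, `n1_s2_uv`, `n1_latency_s1_s`,
#'   `n1_latency_s2_s`, `gating_ratio`, `gating_diff_uv`, `n_trials_used`.
#' @export
erp_session_metrics <- function(recording, events, channel = 1,
                                pre_s = 0.2, post_s = 0.3,
                                search_window = c(0.01, 0.1),
                                reject_uv = Inf) {
  ep1 <- extract_epochs(recording, events, "click1", pre_s, post_s,
                        channel = channel, reject_uv = reject_uv)
  ep2 <- extract_epochs(recording, events, "click2", pre_s, post_s,
                        channel = channel, reject_uv = reject_uv)
  m1 <- measure_n1(average_erp(ep1), search_window[1], search_window[2])
  m2 <- measure_n1(average_erp(ep2), search_window[1], search_window[2])
  data.frame(
    n1_s1_uv = m1$amplitude_uv, n1_s2_uv = m2$amplitude_uv,
    n1_latency_s1_s = m1$latency_s, n1_latency_s2_s = m2$latency_s,
    gating_ratio = gating_ratio(m1$amplitude_uv, m2$amplitude_uv),
    gating_diff_uv = m1$amplitude_uv - m2$amplitude_uv,
    n_trials_used = n_epochs(ep1))
}
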