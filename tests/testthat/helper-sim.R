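# Builders for hand-made recordings and epoch sets used across tests.

make_recording <- function(data, fs = 1000, start_s = 0,
                           channels = colnames(data) %||% "AC") {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  colnames(data) <- channels
  structure(list(data = data, fs = fs, start_s = start_s,
                 channels = channels),
            class = "eeg_recording")
}

make_epochs <- function(m, fs = 1000, pre_s = 0, baseline_window = NULL) {
  times <- (seq_len(ncol(m)) - 1) / fs - pre_s
  if (is.null(baseline_window)) baseline_window <- times[c(1, 2)]
  structure(m, times = times, fs = fs,
            info = data.frame(trial_id = seq_len(nrow(m)), opto = FALSE,
                              onset_s = 0),
            baseline_window = baseline_window,
            rejections = c(edge = 0L, amplitude = 0L),
            class = c("epoch_set", "matrix"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Noise-free parameter set: isolates the deterministic signal components.
silent_params <- function(...) {
  condition_params(noise_sd_uv = 0, basal_gamma_sd_uv = 0, ...)
}

# One simulated EEG session pair (double-click + steady-state) summarised
# into the headline metrics, at reduced trial counts.
session_summary <- function(label, seed, erp_trials = 30, assr_trials = 20) {
  p <- preset_params(label)
  e <- build_erp_protocol(erp_trials)
  rec <- synth_continuous(e$protocol, e$events, p, seed = seed)
  em <- erp_session_metrics(rec, e$events)
  a <- build_assr_protocol(assr_trials)
  reca <- synth_continuous(a$protocol, a$events, p, seed = seed + 1L)
  am <- assr_session_metrics(reca, a$events, freqs_hz = seq(30, 80, 5))
  c(n1 = em$n1_s1_uv, gating = em$gating_ratio,
    basal_gamma = am$basal_gamma_uv2, itc40 = am$itc40_mp)
}
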