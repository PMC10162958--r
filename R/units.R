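#' Peristimulus time histogram
#'
#' Spike timestamps are aligned to each train onset, pooled across trains,
#' grouped into bins (20 ms by default), and divided by `n_trains *
#' bin_s` to obtain firing rates in Hz. The rates conserve the pooled
#' spike count exactly: `sum(rates) * bin_s * n_trials` equals the number
#' of pooled spikes in the window.
#'
#' @param spike_times Sorted spike timestamps (s) for one unit.
#' @param train_onsets Train onset times (s); must be non-empty.
#' @param window_s Length-2 analysis window relative to onset (default
#'   `c(-2, 3)`, covering baseline, train, and offset response).
#' @param bin_s Bin width (s); must divide the window length.
#' @param unit_id,label Optional metadata carried on the result.
#' @return A `psth`: list with `bin_edges_s`, `rates_hz`, `counts`,
#'   `n_trials`, `unit_id`, `label`.
#' @export
psth <- function(spike_times, train_onsets, window_s = c(-2, 3),
                 bin_s = 0.02, unit_id = NULL, label = NULL) {
  if (!length(train_onsets)) stop("empty train list", call. = FALSE)
  wlen <- diff(window_s)
  nb <- wlen / bin_s
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_s must divide the window length", call. = FALSE)
  nb <- as.integer(round(nb))
  rel <- unlist(lapply(train_onsets, function(o) {
    s <- spike_times[spike_times >= o + window_s[1] &
                       spike_times < o + window_s[2]]
    s - o
  }))
  counts <- integer(nb)
  if (length(rel)) {
    bi <- pmax(1L, pmin(nb, floor((rel - window_s[1]) / bin_s) + 1L))
    tb <- tabulate(bi, nbins = nb)
    counts <- tb
  }
  n_trials <- length(train_onsets)
  structure(list(bin_edges_s = window_s[1] + (0:nb) * bin_s,
                 rates_hz = counts / (n_trials * bin_s),
                 counts = counts, n_trials = n_trials,
                 unit_id = unit_id, label = label),
            class = "psth")
}

#' Firing rates in the baseline, initial, and maintenance windows
#'
#' Pooled spike count per window divided by `n_trains * window length`,
#' plus the In/BL and MP/BL rate ratios. A zero baseline rate flags the
#' ratios undefined (`NA`) rather than infinite.
#'
#' @param spike_times Spike timestamps (s) for one unit.
#' @param train_onsets Train onset times (s).
#' @param windows A [phase_windows()] object.
#' @return One-row data frame: `bl_hz`, `in_hz`, `mp_hz`, `ratio_in_bl`,
#'   `ratio_mp_bl`, `ratios_defined`.
#' @export
phase_rates <- function(spike_times, train_onsets,
                        windows = phase_windows()) {
  if (!length(train_onsets)) stop("empty train list", call. = FALSE)
  rate_in <- function(win) {
    cnt <- sum(vapply(train_onsets, function(o) {
      sum(spike_times >= o + win[1] & spike_times < o + win[2])
    }, numeric(1)))
    cnt / (length(train_onsets) * diff(win))
  }
  bl <- rate_in(windows$bl)
  ini <- rate_in(windows$initial)
  mp <- rate_in(windows$maintenance)
  defined <- bl > 0
  data.frame(bl_hz = bl, in_hz = ini, mp_hz = mp,
             ratio_in_bl = if (defined) ini / bl else NA_real_,
             ratio_mp_bl = if (defined) mp / bl else NA_real_,
             ratios_defined = defined)
}

#' Classify units as opto-suppressed (putative PV+ interneurons)
#'
#' The suppression index is `(rate_opto - rate_noopto) / (rate_opto +
#' rate_noopto)`, in `[-1, 1]`; a unit is flagged opto-suppressed when the
#' index falls below `-threshold`. Units silent in both conditions are
#' unclassifiable (`NA`).
#'
#' @param rate_noopto_hz,rate_opto_hz In-train firing rates without / with
#'   optogenetic inhibition (vectorized).
#' @param threshold Classification threshold on the index (default 0.5).
#' @return Data frame: `suppression_index`, `opto_suppressed`.
#' @export
classify_opto_suppressed <- function(rate_noopto_hz, rate_opto_hz,
                                     threshold = 0.5) {
  if (any(rate_noopto_hz < 0) || any(rate_opto_hz < 0))
    stop("rates must be >= 0", call. = FALSE)
  tot <- rate_noopto_hz + rate_opto_hz
  idx <- ifelse(tot > 0, (rate_opto_hz - rate_noopto_hz) / tot, NA_real_)
  data.frame(suppression_index = idx,
             opto_suppressed = ifelse(is.na(idx), NA, idx < -threshold))
}

#' Per-unit opto classification for a simulated/recorded session
#'
#' Computes each unit's in-train firing rate separately for opto and
#' no-opto trials and applies [classify_opto_suppressed()]. Ground-truth
#' PV labels are attached when present.
#'
#' @param spike_data A `spike_data` object (see [synth_spike_trains()]).
#' @param window_s In-train rate window relative to onset (default the
#'   full train, `c(0, 2)`).
#' @param threshold Suppression-index threshold.
#' @return Data frame per unit: `unit_id`, `rate_noopto_hz`,
#'   `rate_opto_hz`, `suppression_index`, `opto_suppressed`, `pv`.
#' @export
unit_opto_classification <- function(spike_data, window_s = c(0, 2),
                                     threshold = 0.5) {
  stopifnot(inherits(spike_data, "spike_data"))
  on_no <- spike_data$onsets[!spike_data$opto]
  on_op <- spike_data$onsets[spike_data$opto]
  if (!length(on_no) || !length(on_op))
    stop("need both opto and no-opto trials", call. = FALSE)
  rate <- function(st, ons) {
    cnt <- sum(vapply(ons, function(o) {
      sum(st >= o + window_s[1] & st < o + window_s[2])
    }, numeric(1)))
    cnt / (length(ons) * diff(window_s))
  }
  ids <- spike_data$units$unit_id
  r_no <- r_op <- numeric(length(ids))
  for (i in seq_along(ids)) {
    st <- spike_data$spikes$spike_time_s[spike_data$spikes$unit_id == ids[i]]
    r_no[i] <- rate(st, on_no)
    r_op[i] <- rate(st, on_op)
  }
  cl <- classify_opto_suppressed(r_no, r_op, threshold)
  data.frame(unit_id = ids, rate_noopto_hz = r_no, rate_opto_hz = r_op,
             cl, pv = spike_data$units$pv)
}

#' Spread statistics of an across-unit firing-rate distribution
#'
#' @param units_rates Numeric vector of per-unit rates (>= 2 units).
#' @return Named vector: `mean`, `sd`, `iqr`.
#' @export
rate_distribution_stats <- function(units_rates) {
  if (length(units_rates) < 2) stop("need >= 2 units", call. = FALSE)
  c(mean = mean(units_rates), sd = stats::sd(units_rates),
    iqr = unname(diff(stats::quantile(units_rates, c(0.25, 0.75)))))
}

#' Tidy per-unit rate table by phase and opto condition
#'
#' Phase rates (BL/In/MP) per unit, computed separately over opto and
#' no-opto trials. Units with baseline rate below `min_bl_hz` in a subset
#' are flagged low-rate (their ratios are unstable and excluded from
#' ratio summaries downstream).
#'
#' @param spike_data A `spike_data` object.
#' @param windows A [phase_windows()] object.
#' @param min_bl_hz Low-rate flag threshold (default 0.1 Hz).
#' @return Long data frame: `unit_id`, `pv`, `opto`, `bl_hz`, `in_hz`,
#'   `mp_hz`, `ratio_in_bl`, `ratio_mp_bl`, `low_rate`.
#' @export
unit_rate_table <- function(spike_data, windows = phase_windows(),
                            min_bl_hz = 0.1) {
  stopifnot(inherits(spike_data, "spike_data"))
  subsets <- list(`FALSE` = spike_data$onsets[!spike_data$opto],
                  `TRUE` = spike_data$onsets[spike_data$opto])
  subsets <- subsets[lengths(subsets) > 0]
  out <- list()
  for (i in seq_len(nrow(spike_data$units))) {
    uid <- spike_data$units$unit_id[i]
    st <- spike_data$spikes$spike_time_s[spike_data$spikes$unit_id == uid]
    for (s in names(subsets)) {
      pr <- phase_rates(st, subsets[[s]], windows)
      out[[length(out) + 1]] <- data.frame(
        unit_id = uid, pv = spike_data$units$pv[i],
        opto = as.logical(s), pr,
        low_rate = pr$bl_hz < min_bl_hz)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g s, %d trials, peak %g Hz\n",
              length(x$rates_hz), diff(x$bin_edges_s[1:2]), x$n_trials,
              max(x$rates_hz)))
  invisible(x)
}
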