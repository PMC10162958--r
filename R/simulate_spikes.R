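#' Simulate single-unit spike trains for a steady-state session
#'
#' Each unit is an inhomogeneous Poisson process generated by thinning a
#' homogeneous process at the unit's peak rate. The intensity is
#' `lambda(t) = lambda_base * m_stim(t) * m_opto(t)`, where `m_stim` equals
#' `in_gain` during the first 50 ms of a train, `mp_gain * (1 +
#' mp_mod_depth * sin(2 pi f0 t_rel))` during 50-2000 ms, and 1 elsewhere;
#' `m_opto` equals `opto_suppression` for PV+ units and `disinhibition`
#' for other units during opto-flagged trains, and 1 otherwise.
#'
#' Baseline rates are drawn log-normally across units and then shrunk
#' toward their mean by `ly_tightening` (a factor of 0.5 exactly halves
#' the across-unit SD). A fraction `pv_fraction` of units (rounded) is
#' flagged PV+. Spike times are reported on a 40 kHz grid (0.025 ms
#' resolution), duplicates removed.
#'
#' @param protocol An `assr_train` `stim_protocol`.
#' @param events Its event table.
#' @param opto_flags Logical per-trial flags; defaults to the `opto`
#'   column of the train rows of `events`.
#' @param params A [condition_params()] object.
#' @param seed Optional integer for reproducibility.
#' @param span_s Session length in seconds; defaults to the last train
#'   onset plus one inter-train interval.
#' @return A `spike_data` object: list with `spikes` (data frame
#'   `unit_id`, `spike_time_s`), `units` (data frame `unit_id`, `pv`,
#'   `base_rate_hz`), `onsets`, `opto`, `train_dur_s`, `span_s`.
#' @export
synth_spike_trains <- function(protocol, events, opto_flags = NULL,
                               params = condition_params(), seed = NULL,
                               span_s = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(params, "condition_params"))
  if (protocol$kind != "assr_train")
    stop("spike simulation is defined for assr_train protocols", call. = FALSE)
  trains <- events[events$event_type == "train_start", , drop = FALSE]
  onsets <- trains$onset_s
  if (is.null(opto_flags)) opto_flags <- trains$opto
  if (length(opto_flags) != length(onsets))
    stop("opto_flags length must equal the number of trains", call. = FALSE)
  span_s <- span_s %||% (max(onsets) + protocol$iti_s)
  f0 <- protocol$click_rate_hz
  dur <- protocol$train_dur_s

  build <- function() {
    n_units <- as.integer(params$n_units)
    n_pv <- as.integer(round(params$pv_fraction * n_units))
    pv <- rep(FALSE, n_units)
    if (n_pv > 0) pv[sample.int(n_units, n_pv)] <- TRUE
    base <- stats::rlnorm(n_units, params$rate_meanlog, params$rate_sdlog)
    base <- mean(base) + params$ly_tightening * (base - mean(base))

    mod_at <- function(t, is_pv) {
      # trial index of each candidate time; windows never overlap (iti > dur)
      k <- findInterval(t, onsets)
      off <- t - onsets[pmax(k, 1L)]
      in_train <- k >= 1L & off < dur
      m <- rep(1, length(t))
      ini <- in_train & off < 0.05
      mp <- in_train & off >= 0.05
      m[ini] <- params$in_gain
      m[mp] <- params$mp_gain *
        (1 + params$mp_mod_depth * sin(2 * pi * f0 * off[mp]))
      is_opto <- in_train & opto_flags[pmax(k, 1L)]
      m[is_opto] <- m[is_opto] *
        if (is_pv) params$opto_suppression else params$disinhibition
      m
    }
    mod_max <- function(is_pv) {
      g <- max(params$in_gain, params$mp_gain * (1 + params$mp_mod_depth), 1)
      g * if (is_pv) 1 else max(1, params$disinhibition)
    }

    sp <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      lam_max <- base[u] * mod_max(pv[u])
      if (lam_max < 0) stop("simulation error: negative rate", call. = FALSE)
      n_cand <- stats::rpois(1, lam_max * span_s)
      if (n_cand == 0) { sp[[u]] <- numeric(0); next }
      t_cand <- sort(stats::runif(n_cand, 0, span_s))
      p_keep <- base[u] * mod_at(t_cand, pv[u]) / lam_max
      keep <- stats::runif(n_cand) < p_keep
      tt <- round(t_cand[keep] * 40000) / 40000
      sp[[u]] <- unique(tt)
    }
    spikes <- data.frame(
      unit_id = rep(seq_len(n_units), lengths(sp)),
      spike_time_s = unlist(sp))
    structure(
      list(spikes = spikes,
           units = data.frame(unit_id = seq_len(n_units), pv = pv,
                              base_rate_hz = base),
           onsets = onsets, opto = opto_flags,
           train_dur_s = dur, span_s = span_s),
      class = "spike_data")
  }
  maybe_with_seed(seed, build)
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d units (%d PV+), %d spikes over %g s, %d trains\n",
              nrow(x$units), sum(x$units$pv), nrow(x$spikes), x$span_s,
              length(x$onsets)))
  invisible(x)
}
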