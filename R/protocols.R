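#' Build a double-click (paired-stimulus) ERP protocol
#'
#' Constructs the stimulus timeline of a sensory-gating session: `n_trials`
#' pairs of identical clicks (S1, S2), with consecutive pair onsets `iti_s`
#' apart and `pair_gap_s` between the two clicks of a pair. The canonical
#' screw-EEG session uses 300 pairs spaced 8 s apart.
#'
#' @param n_trials Number of click pairs (>= 1).
#' @param iti_s Inter-trial interval in seconds between consecutive S1
#'   onsets; must exceed `pair_gap_s`.
#' @param pair_gap_s Within-pair S1-to-S2 interval in seconds (default 0.5 s,
#'   the standard double-click gating convention).
#' @return A list with components `protocol` (a `stim_protocol`) and
#'   `events` (a data frame with columns `onset_s`, `event_type`
#'   (`"click1"`/`"click2"`), `trial_id`, `opto`). The first S1 falls at 0 s.
#' @export
#' @examples
#' sess <- build_erp_protocol(10, iti_s = 8, pair_gap_s = 0.5)
#' table(sess$events$event_type)
build_erp_protocol <- function(n_trials, iti_s = 8, pair_gap_s = 0.5) {
  if (length(n_trials) != 1 || !is.finite(n_trials) || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("invalid protocol: n_trials must be a positive integer", call. = FALSE)
  if (!is.finite(iti_s) || !is.finite(pair_gap_s) || pair_gap_s <= 0 ||
      iti_s <= pair_gap_s)
    stop("invalid protocol: need iti_s > pair_gap_s > 0", call. = FALSE)
  n_trials <- as.integer(n_trials)
  protocol <- structure(
    list(kind = "erp_pair", n_trials = n_trials, iti_s = iti_s,
         pair_gap_s = pair_gap_s, level_db = 85),
    class = "stim_protocol")
  on1 <- (seq_len(n_trials) - 1) * iti_s
  events <- data.frame(
    onset_s = as.vector(rbind(on1, on1 + pair_gap_s)),
    event_type = rep(c("click1", "click2"), n_trials),
    trial_id = rep(seq_len(n_trials), each = 2),
    opto = FALSE,
    stringsAsFactors = FALSE)
  list(protocol = protocol, events = events)
}

#' Build a 40 Hz click-train (steady-state) protocol
#'
#' Constructs the timeline of an auditory steady-state session: `n_trials`
#' trains of clicks at `click_rate_hz` lasting `train_dur_s`, train onsets
#' `iti_s` apart. The canonical sessions are 300 trains of 80 clicks over
#' 2 s at 40 Hz, 10 s apart (screw EEG), or 600 such trains with 50%
#' delivered under optogenetic silencing (tetrode).
#'
#' @param n_trials Number of click trains.
#' @param click_rate_hz Click repetition rate within a train (Hz).
#' @param train_dur_s Train duration in seconds; `click_rate_hz *
#'   train_dur_s` must be a whole number of clicks.
#' @param iti_s Seconds between consecutive train onsets; must exceed
#'   `train_dur_s`.
#' @return A list with `protocol` and `events`; events contain one
#'   `train_start` row per trial plus one `click` row per click.
#' @export
#' @examples
#' sess <- build_assr_protocol(3, 40, 2, 10)
#' sum(sess$events$event_type == "click") # 240
build_assr_protocol <- function(n_trials, click_rate_hz = 40, train_dur_s = 2,
                                iti_s = 10) {
  if (length(n_trials) != 1 || !is.finite(n_trials) || n_trials < 1 ||
      n_trials != round(n_trials))
    stop("invalid protocol: n_trials must be a positive integer", call. = FALSE)
  if (!is.finite(click_rate_hz) || click_rate_hz <= 0 || train_dur_s <= 0)
    stop("invalid protocol: non-positive rate or duration", call. = FALSE)
  n_clicks <- click_rate_hz * train_dur_s
  if (abs(n_clicks - round(n_clicks)) > 1e-9)
    stop("invalid protocol: click_rate_hz * train_dur_s must be integral",
         call. = FALSE)
  n_clicks <- as.integer(round(n_clicks))
  if (iti_s <= train_dur_s)
    stop("invalid protocol: iti_s must exceed train_dur_s (trains overlap)",
         call. = FALSE)
  n_trials <- as.integer(n_trials)
  protocol <- structure(
    list(kind = "assr_train", n_trials = n_trials,
         click_rate_hz = click_rate_hz, train_dur_s = train_dur_s,
         iti_s = iti_s, n_clicks = n_clicks, level_db = 85),
    class = "stim_protocol")
  on <- (seq_len(n_trials) - 1) * iti_s
  trains <- data.frame(
    onset_s = on, event_type = "train_start", trial_id = seq_len(n_trials),
    opto = FALSE, stringsAsFactors = FALSE)
  clicks <- data.frame(
    onset_s = rep(on, each = n_clicks) +
      rep((seq_len(n_clicks) - 1) / click_rate_hz, n_trials),
    event_type = "click",
    trial_id = rep(seq_len(n_trials), each = n_clicks),
    opto = FALSE, stringsAsFactors = FALSE)
  events <- rbind(trains, clicks)
  events <- events[order(events$onset_s,
                         match(events$event_type, c("train_start", "click"))), ]
  rownames(events) <- NULL
  list(protocol = protocol, events = events)
}

#' Pseudorandom optogenetic trial assignment
#'
#' Flags a given fraction of trials for delivery under optogenetic
#' inhibition, in a pseudorandom sequence with bounded runs: no more than
#' `max_run` consecutive trials share a flag (so stimulation never clusters),
#' matching interleaved opto/no-opto session designs.
#'
#' The run-length bound applies only when both flag values occur (a fraction
#' of 0 or 1 trivially returns a constant sequence).
#'
#' @param n_trials Number of trials.
#' @param fraction Proportion of trials flagged `TRUE`; exactly
#'   `round(fraction * n_trials)` flags are set.
#' @param max_run Longest permitted run of identical flags (>= 1).
#' @param seed Optional integer; fixes the sequence reproducibly without
#'   disturbing the caller's RNG stream.
#' @return Logical vector of length `n_trials`.
#' @export
assign_opto_flags <- function(n_trials, fraction = 0.5, max_run = 4,
                              seed = NULL) {
  if (n_trials < 1 || n_trials != round(n_trials))
    stop("assignment error: n_trials must be a positive integer", call. = FALSE)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("assignment error: fraction must lie in [0, 1]", call. = FALSE)
  if (max_run < 1) stop("assignment error: max_run must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  n_true <- as.integer(round(fraction * n_trials))
  n_false <- n_trials - n_true
  if (n_true == 0L) return(rep(FALSE, n_trials))
  if (n_false == 0L) return(rep(TRUE, n_trials))

  # Feasible iff each type fits into max_run-sized blocks separated by the
  # other type; checked incrementally during construction.
  feas <- function(a, b, run_true, run_false) {
    a <= max_run * (b + 1) - run_true && b <= max_run * (a + 1) - run_false
  }
  if (!feas(n_true, n_false, 0, 0))
    stop("assignment error: no sequence satisfies fraction/max_run", call. = FALSE)

  draw <- function() {
    a <- n_true; b <- n_false
    run_val <- NA; run_len <- 0L
    out <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      ok_true <- a > 0 && !(isTRUE(run_val) && run_len >= max_run) &&
        feas(a - 1L, b, if (isTRUE(run_val)) run_len + 1L else 1L, 0L)
      ok_false <- b > 0 && !(identical(run_val, FALSE) && run_len >= max_run) &&
        feas(a, b - 1L, 0L, if (identical(run_val, FALSE)) run_len + 1L else 1L)
      if (!ok_true && !ok_false)
        stop("assignment error: no feasible continuation", call. = FALSE)
      v <- if (ok_true && ok_false) {
        stats::runif(1) < a / (a + b)
      } else ok_true
      out[i] <- v
      run_len <- if (identical(v, run_val)) run_len + 1L else 1L
      run_val <- v
      if (v) a <- a - 1L else b <- b - 1L
    }
    out
  }
  maybe_with_seed(seed, draw)
}

#' Randomized cross-over treatment design
#'
#' Every subject receives every treatment exactly once, in an independently
#' randomized session order (each subject is its own control).
#'
#' @param subject_ids Vector of subject identifiers (>= 1).
#' @param treatments Character vector of distinct treatment labels (>= 2).
#' @param seed Optional integer for a reproducible randomization.
#' @param doses Optional named numeric vector mapping treatment labels to a
#'   dose in mg/kg; unmatched labels get `NA`.
#' @return A `condition_design` data frame with columns `subject_id`,
#'   `session_index`, `treatment`, `dose_mg_kg`.
#' @export
build_crossover_design <- function(subject_ids, treatments, seed = NULL,
                                   doses = NULL) {
  if (length(subject_ids) < 1) stop("design error: need >= 1 subject", call. = FALSE)
  if (length(treatments) < 2) stop("design error: need >= 2 treatments", call. = FALSE)
  if (anyDuplicated(treatments))
    stop("design error: duplicate treatment labels", call. = FALSE)
  draw <- function() {
    do.call(rbind, lapply(subject_ids, function(s) {
      data.frame(subject_id = s,
                 session_index = seq_along(treatments),
                 treatment = sample(treatments),
                 stringsAsFactors = FALSE)
    }))
  }
  d <- maybe_with_seed(seed, draw)
  d$dose_mg_kg <- if (is.null(doses)) NA_real_ else unname(doses[d$treatment])
  rownames(d) <- NULL
  class(d) <- c("condition_design", "data.frame")
  d
}

#' Attach optogenetic flags to a steady-state event table
#'
#' Sets the `opto` column of every event in a flagged trial and inserts
#' `opto_on`/`opto_off` marker rows bracketing each flagged train.
#'
#' @param protocol An `assr_train` protocol.
#' @param events Its event table.
#' @param flags Logical vector, one per trial (see [assign_opto_flags()]).
#' @param lead_s,lag_s Seconds the light extends before train onset / after
#'   train offset (defaults 0).
#' @return The augmented event table, sorted by onset.
#' @export
set_opto_events <- function(protocol, events, flags, lead_s = 0, lag_s = 0) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$kind != "assr_train")
    stop("opto flags apply to assr_train protocols", call. = FALSE)
  if (length(flags) != protocol$n_trials)
    stop("flags length must equal n_trials", call. = FALSE)
  events$opto <- flags[events$trial_id]
  on <- events$onset_s[events$event_type == "train_start"]
  flagged <- which(flags)
  if (length(flagged)) {
    marks <- data.frame(
      onset_s = c(on[flagged] - lead_s,
                  on[flagged] + protocol$train_dur_s + lag_s),
      event_type = rep(c("opto_on", "opto_off"), each = length(flagged)),
      trial_id = rep(flagged, 2),
      opto = TRUE, stringsAsFactors = FALSE)
    events <- rbind(events, marks)
  }
  prio <- c("opto_on", "train_start", "click", "opto_off")
  events <- events[order(events$onset_s, match(events$event_type, prio)), ]
  rownames(events) <- NULL
  events
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", x$kind, "\n")
  if (x$kind == "erp_pair") {
    cat(sprintf("  %d click pairs, ITI %g s, pair gap %g s\n",
                x$n_trials, x$iti_s, x$pair_gap_s))
  } else {
    cat(sprintf("  %d trains of %d clicks @ %g Hz over %g s, ITI %g s\n",
                x$n_trials, x$n_clicks, x$click_rate_hz, x$train_dur_s, x$iti_s))
  }
  invisible(x)
}
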