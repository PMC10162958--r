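# Plain-text serialization: CSV for tables and continuous traces, YAML for
# protocols, JSON for ground truth.

#' Write / read an event table as CSV
#'
#' Columns: `onset_s`, `event_type`, `trial_id`, `opto`.
#' @param events Event table.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("onset_s", "event_type", "trial_id", "opto")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev$opto <- as.logical(ev$opto)
  ev
}

#' Write / read a cross-over design as CSV
#'
#' Columns: `subject_id`, `session_index`, `treatment`, `dose_mg_kg`.
#' @param design A `condition_design`.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$dose_mg_kg <- as.numeric(d$dose_mg_kg)
  class(d) <- c("condition_design", "data.frame")
  d
}

#' Write / read a continuous recording in the package CSV dialect
#'
#' One `time_s` column plus one column per channel (microvolts). On read,
#' the sampling rate is recovered from the median time step.
#'
#' @param recording An `eeg_recording`.
#' @param path File path.
#' @export
write_recording_csv <- function(recording, path) {
  n <- nrow(recording$data)
  d <- data.frame(time_s = recording$start_s + (seq_len(n) - 1) / recording$fs)
  d <- cbind(d, as.data.frame(recording$data))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  d <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(d$time_s))
  chans <- setdiff(names(d), "time_s")
  structure(list(data = as.matrix(d[chans]), fs = round(fs),
                 start_s = d$time_s[1], channels = chans),
            class = "eeg_recording")
}

#' Write / read spike timestamps as CSV
#'
#' Columns: `unit_id`, `spike_time_s`.
#' @param spike_data A `spike_data` object or a data frame with those
#'   columns.
#' @param path File path.
#' @export
write_spikes_csv <- function(spike_data, path) {
  d <- if (inherits(spike_data, "spike_data")) spike_data$spikes else spike_data
  utils::write.csv(d[, c("unit_id", "spike_time_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) utils::read.csv(path)

#' Export simulation ground truth as JSON
#'
#' @param recording An `eeg_recording` produced by [synth_continuous()].
#' @param path File path.
#' @export
write_ground_truth_json <- function(recording, path) {
  gt <- attr(recording, "ground_truth")
  if (is.null(gt)) stop("recording carries no ground truth", call. = FALSE)
  gt$params <- unclass(gt$params)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize / restore a stimulus protocol as YAML
#'
#' @param protocol A `stim_protocol`.
#' @param path File path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  structure(p, class = "stim_protocol")
}
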