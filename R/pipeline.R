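#' Configuration for the end-to-end simulation/analysis pipeline
#'
#' Defaults run a scaled-down version of the two studies: a pharmacological
#' cross-over EEG study (two channels, four treatments per subject) and an
#' optogenetic tetrode study (50% opto trials, two treatments). Trial and
#' subject counts are reduced from the full protocols (300/600 trials,
#' 19/8 subjects) so the pipeline runs in minutes on a laptop; all counts
#' are configurable back to full scale.
#'
#' @param seed Master seed; every per-session seed derives from it.
#' @param n_subjects Subjects in the EEG study.
#' @param treatments Treatment labels understood by [preset_params()].
#' @param erp_trials,assr_trials Trials per ERP / steady-state session.
#' @param channels EEG channel labels.
#' @param tetrode List: `n_subjects`, `n_trials`, `n_units`, `treatments`
#'   (labels understood by [tetrode_presets()]).
#' @param freqs_hz Wavelet grid for the steady-state metrics.
#' @param make_plots Write summary figures (PNG) alongside the tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            n_subjects = 6,
                            treatments = c("vehicle", "MK801",
                                           "MK801+LY1", "MK801+LY3"),
                            erp_trials = 40, assr_trials = 30,
                            channels = c("AC", "mPFC"),
                            tetrode = list(n_subjects = 4, n_trials = 40,
                                           n_units = 20,
                                           treatments = c("vehicle", "LY3")),
                            freqs_hz = seq(30, 80, by = 5),
                            make_plots = FALSE) {
  structure(list(seed = seed, n_subjects = n_subjects,
                 treatments = treatments, erp_trials = erp_trials,
                 assr_trials = assr_trials, channels = channels,
                 tetrode = tetrode, freqs_hz = freqs_hz,
                 make_plots = make_plots),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown fields raise an error naming the offending key.
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("config schema violation at field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, cfg)
}

.session_seed <- function(seed, i, j) {
  as.integer((seed * 7919 + i * 104729 + j * 1299709) %% .Machine$integer.max)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates every session of both studies under the configured condition
#' presets, computes ERP, spectral, and unit metrics, runs the
#' least-squares-means contrasts (EEG study) and the two-way
#' optogenetics-by-drug analysis (tetrode study), and writes tidy CSV
#' tables plus a JSON run manifest (and figures when `make_plots` is set)
#' to `out_dir`. Byte-identical outputs are produced for identical
#' configuration and seed.
#'
#' @param config A [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, a list with the EEG metric table, EEG contrasts,
#'   tetrode metric table, tetrode ANOVA table, and unit table.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## --- EEG cross-over study -------------------------------------------
  subjects <- sprintf("m%02d", seq_len(config$n_subjects))
  design <- build_crossover_design(subjects, config$treatments,
                                   seed = config$seed)
  eeg_rows <- list()
  for (r in seq_len(nrow(design))) {
    subj <- design$subject_id[r]
    trt <- design$treatment[r]
    params <- preset_params(trt)
    si <- match(subj, subjects)
    erp_sess <- build_erp_protocol(config$erp_trials)
    rec_e <- synth_continuous(erp_sess$protocol, erp_sess$events, params,
                              channels = config$channels,
                              seed = .session_seed(config$seed, si, 2L * r))
    assr_sess <- build_assr_protocol(config$assr_trials)
    rec_a <- synth_continuous(assr_sess$protocol, assr_sess$events, params,
                              channels = config$channels,
                              seed = .session_seed(config$seed, si, 2L * r + 1L))
    for (ch in config$channels) {
      em <- erp_session_metrics(rec_e, erp_sess$events, channel = ch)
      ep1 <- extract_epochs(rec_e, erp_sess$events, "click1", 0.5, 0.4,
                            channel = ch)
      evoked_gamma <- band_power(
        morlet_tf(ep1, seq(30, 80, by = 5)), c(30, 80), c(0, 0.1), "evoked")
      am <- assr_session_metrics(rec_a, assr_sess$events, channel = ch,
                                 freqs_hz = config$freqs_hz)
      vals <- c(n1_s1 = em$n1_s1_uv, n1_s2 = em$n1_s2_uv,
                latency_s1 = em$n1_latency_s1_s,
                latency_s2 = em$n1_latency_s2_s,
                gating_ratio = em$gating_ratio,
                gating_diff = em$gating_diff_uv,
                evoked_gamma = evoked_gamma,
                basal_gamma = am$basal_gamma_uv2,
                power40_in = am$power40_in, power40_mp = am$power40_mp,
                itc40_in = am$itc40_in, itc40_mp = am$itc40_mp)
      eeg_rows[[length(eeg_rows) + 1]] <- data.frame(
        subject_id = subj, session_index = design$session_index[r],
        channel = ch, treatment = trt, metric = names(vals),
        value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  eeg_metrics <- do.call(rbind, eeg_rows)

  eeg_contrasts <- do.call(rbind, lapply(unique(eeg_metrics$metric), function(m) {
    do.call(rbind, lapply(config$channels, function(ch) {
      tab <- eeg_metrics[eeg_metrics$channel == ch, ]
      refs <- intersect(c("vehicle", "MK801"), unique(tab$treatment))
      cs <- lsmeans_contrasts(tab, m, reference_labels = refs)
      cs$channel <- ch
      cs
    }))
  }))

  ## --- Optogenetic tetrode study --------------------------------------
  tcfg <- config$tetrode
  tet_rows <- list(); unit_rows <- list()
  for (si in seq_len(tcfg$n_subjects)) {
    for (ti in seq_along(tcfg$treatments)) {
      trt <- tcfg$treatments[ti]
      params <- tetrode_presets(trt)
      params$n_units <- tcfg$n_units
      sess <- build_assr_protocol(tcfg$n_trials)
      sd_seed <- .session_seed(config$seed, 1000L + si, ti)
      flags <- assign_opto_flags(tcfg$n_trials, 0.5, 4, seed = sd_seed)
      events <- set_opto_events(sess$protocol, sess$events, flags)
      rec <- synth_continuous(sess$protocol, events, params,
                              channels = "mPFC", seed = sd_seed + 1L)
      spikes <- synth_spike_trains(sess$protocol, events, flags, params,
                                   seed = sd_seed + 2L)
      for (op in c(FALSE, TRUE)) {
        am <- assr_session_metrics(rec, events, channel = "mPFC",
                                   freqs_hz = config$freqs_hz,
                                   trial_subset = (flags == op))
        vals <- c(power40_in = am$power40_in, power40_mp = am$power40_mp,
                  itc40_in = am$itc40_in, itc40_mp = am$itc40_mp,
                  basal_gamma = am$basal_gamma_uv2)
        tet_rows[[length(tet_rows) + 1]] <- data.frame(
          electrode_id = sprintf("s%02d", si), treatment = trt, opto = op,
          metric = names(vals), value = unname(vals),
          stringsAsFactors = FALSE)
      }
      ut <- unit_rate_table(spikes)
      ut$subject <- sprintf("s%02d", si)
      ut$treatment <- trt
      unit_rows[[length(unit_rows) + 1]] <- ut
    }
  }
  tet_metrics <- do.call(rbind, tet_rows)
  unit_metrics <- do.call(rbind, unit_rows)
  tet_anova <- do.call(rbind, lapply(unique(tet_metrics$metric), function(m) {
    a <- twoway_opto_drug(tet_metrics, m)
    a$metric <- m
    a
  }))

  ## --- Outputs ---------------------------------------------------------
  utils::write.csv(eeg_metrics, file.path(out_dir, "eeg_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(eeg_contrasts, file.path(out_dir, "eeg_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(tet_metrics, file.path(out_dir, "tetrode_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(tet_anova, file.path(out_dir, "tetrode_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(unit_metrics, file.path(out_dir, "unit_metrics.csv"),
                   row.names = FALSE)
  write_design_csv(design, file.path(out_dir, "design.csv"))
  manifest <- list(package = "assrtools",
                   version = as.character(utils::packageVersion("assrtools")),
                   seed = config$seed,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(config$make_plots)) .pipeline_plots(eeg_metrics, out_dir)

  invisible(list(eeg_metrics = eeg_metrics, eeg_contrasts = eeg_contrasts,
                 tetrode_metrics = tet_metrics, tetrode_anova = tet_anova,
                 unit_metrics = unit_metrics, design = design))
}

# Bar summaries of the headline EEG metrics (mean +/- SEM per condition).
.pipeline_plots <- function(eeg_metrics, out_dir) {
  for (m in c("n1_s1", "gating_ratio", "basal_gamma", "itc40_mp")) {
    s <- condition_summary(eeg_metrics[eeg_metrics$channel ==
                                         eeg_metrics$channel[1], ], m)
    p <- ggplot2::ggplot(s, ggplot2::aes(x = treatment, y = mean)) +
      ggplot2::geom_col(fill = "grey70", colour = "black") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem), width = 0.2) +
      ggplot2::labs(y = m, x = NULL) +
      ggplot2::theme_classic()
    ggplot2::ggsave(file.path(out_dir, paste0("summary_", m, ".png")), p,
                    width = 4, height = 3, dpi = 120)
  }
  invisible(NULL)
}
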