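#' Simulation parameters for one experimental condition
#'
#' Bundles every knob of the synthetic-session generator: ERP shape and
#' gating, background noise, basal gamma, 40 Hz entrainment, and the
#' single-unit population. Defaults describe the vehicle (control)
#' condition; see [preset_params()] and [tetrode_presets()] for the
#' perturbed conditions.
#'
#' @param fs Sampling rate of the continuous trace (Hz).
#' @param n1_amp_uv Magnitude of the n1 trough of the click-evoked
#'   potential (microvolts, >= 0).
#' @param n1_latency_s n1 latency after click onset (s).
#' @param gating_g Multiplier applied to the second-click response, in
#'   `[0, 1]`; the sensory-gating ground truth (S2/S1 amplitude ratio).
#' @param basal_gamma_sd_uv Standard deviation of the band-limited
#'   (30-80 Hz) background gamma component.
#' @param assr_amp_uv Amplitude of the 40 Hz entrained sinusoid during the
#'   steady-state train.
#' @param assr_kappa Von Mises concentration of the per-trial entrainment
#'   phase; larger means more phase-locked (higher inter-trial coherence).
#' @param initial_boost Multiplier on `assr_amp_uv` during the first 50 ms
#'   of each train (the initial-response transient).
#' @param noise_alpha,noise_sd_uv Spectral exponent and scale of the 1/f
#'   background noise.
#' @param n_units,pv_fraction Number of simulated units and the fraction
#'   flagged as parvalbumin-positive (PV+) interneurons; cortical
#'   populations are 80-90% excitatory, so the default PV fraction is 0.15.
#' @param rate_meanlog,rate_sdlog Log-normal parameters of across-unit
#'   baseline firing rates (Hz).
#' @param in_gain,mp_gain Multiplicative rate modulation during the
#'   initial (0-50 ms) and maintenance (50-2000 ms) phases of a train.
#' @param mp_mod_depth Depth of the 40 Hz sinusoidal rate modulation
#'   during the maintenance phase, in `[0, 1)`.
#' @param opto_suppression Rate multiplier `s` in `[0, 1]` applied to PV+
#'   units during opto-flagged trains (0 = complete silencing).
#' @param disinhibition Rate multiplier `d >= 1` applied to non-PV units
#'   during opto-flagged trains (downstream release from inhibition).
#' @param ly_tightening Shrinkage factor in `(0, 1]` applied to the
#'   across-unit spread of baseline rates (mGluR2/3-agonist effect); 1
#'   leaves the population untouched, 0.5 halves the across-unit SD.
#' @param opto_gamma_gain Multiplier on the basal-gamma amplitude within
#'   opto-flagged trials (PV silencing raises basal gamma).
#' @param opto_kappa_factor Multiplier on `assr_kappa` for opto-flagged
#'   trials (PV silencing degrades 40 Hz phase locking).
#' @return A `condition_params` list.
#' @export
condition_params <- function(fs = 1000,
                             n1_amp_uv = 30, n1_latency_s = 0.04,
                             gating_g = 0.5,
                             basal_gamma_sd_uv = 2,
                             assr_amp_uv = 5, assr_kappa = 8,
                             initial_boost = 2,
                             noise_alpha = 1, noise_sd_uv = 8,
                             n_units = 40, pv_fraction = 0.15,
                             rate_meanlog = log(5), rate_sdlog = 0.6,
                             in_gain = 3, mp_gain = 1.5, mp_mod_depth = 0.3,
                             opto_suppression = 1, disinhibition = 1,
                             ly_tightening = 1,
                             opto_gamma_gain = 1, opto_kappa_factor = 1) {
  p <- list(fs = fs, n1_amp_uv = n1_amp_uv, n1_latency_s = n1_latency_s,
            gating_g = gating_g, basal_gamma_sd_uv = basal_gamma_sd_uv,
            assr_amp_uv = assr_amp_uv, assr_kappa = assr_kappa,
            initial_boost = initial_boost, noise_alpha = noise_alpha,
            noise_sd_uv = noise_sd_uv, n_units = n_units,
            pv_fraction = pv_fraction, rate_meanlog = rate_meanlog,
            rate_sdlog = rate_sdlog, in_gain = in_gain, mp_gain = mp_gain,
            mp_mod_depth = mp_mod_depth, opto_suppression = opto_suppression,
            disinhibition = disinhibition, ly_tightening = ly_tightening,
            opto_gamma_gain = opto_gamma_gain,
            opto_kappa_factor = opto_kappa_factor)
  with(p, {
    stopifnot(fs > 0, n1_amp_uv >= 0, n1_latency_s > 0,
              gating_g >= 0, gating_g <= 1,
              basal_gamma_sd_uv >= 0, assr_amp_uv >= 0, assr_kappa >= 0,
              initial_boost >= 0, noise_alpha >= 0, noise_sd_uv >= 0,
              n_units >= 1, pv_fraction >= 0, pv_fraction <= 1,
              in_gain >= 0, mp_gain >= 0, mp_mod_depth >= 0, mp_mod_depth < 1,
              opto_suppression >= 0, opto_suppression <= 1,
              disinhibition >= 1,
              ly_tightening > 0, ly_tightening <= 1,
              opto_gamma_gain > 0, opto_kappa_factor > 0)
  })
  structure(p, class = "condition_params")
}

# Linear interpolation between two parameter sets on the named fields.
.blend_params <- function(from, to, frac, fields) {
  out <- from
  for (f in fields) out[[f]] <- from[[f]] + frac * (to[[f]] - from[[f]])
  out
}

#' Condition presets for the pharmacological cross-over (screw-EEG) study
#'
#' Maps a treatment label to simulation parameters. The NMDA-antagonist
#' condition (`"MK801"`) lowers n1 amplitude, weakens gating (ratio closer
#' to 1), raises basal gamma, and lowers both 40 Hz amplitude and phase
#' locking. Co-treatment labels of the form `"MK801+LY<dose>"` move every
#' affected parameter back toward vehicle monotonically in dose via the
#' saturating fraction `dose / (dose + 1)`. `"LY<dose>"` alone mildly
#' increases phase locking and lowers basal gamma. Magnitudes are package
#' defaults (the source study reports directions, not effect sizes).
#'
#' @param label One of `"vehicle"`, `"MK801"`, `"MK801+LY<dose>"`,
#'   `"LY<dose>"` (dose in mg/kg, e.g. `"MK801+LY3"`).
#' @return A [condition_params()] object.
#' @export
#' @examples
#' preset_params("MK801")$gating_g
#' preset_params("MK801+LY3")$assr_kappa
preset_params <- function(label) {
  veh <- condition_params()
  mk <- condition_params(n1_amp_uv = 15, gating_g = 0.8,
                         basal_gamma_sd_uv = 3.5,
                         assr_amp_uv = 2.5, assr_kappa = 2)
  fields <- c("n1_amp_uv", "gating_g", "basal_gamma_sd_uv",
              "assr_amp_uv", "assr_kappa")
  if (identical(label, "vehicle")) return(veh)
  if (identical(label, "MK801")) return(mk)
  m <- regmatches(label, regexec("^MK801\\+LY([0-9.]+)$", label))[[1]]
  if (length(m) == 2) {
    dose <- as.numeric(m[2])
    if (!is.finite(dose) || dose <= 0)
      stop("invalid preset dose in label: ", label, call. = FALSE)
    r <- dose / (dose + 1)
    p <- .blend_params(unclass(mk), unclass(veh), r, fields)
    return(do.call(condition_params, p))
  }
  m <- regmatches(label, regexec("^LY([0-9.]+)$", label))[[1]]
  if (length(m) == 2) {
    dose <- as.numeric(m[2])
    r <- dose / (dose + 1)
    p <- veh
    p$assr_kappa <- veh$assr_kappa * (1 + 0.5 * r)
    p$basal_gamma_sd_uv <- veh$basal_gamma_sd_uv * (1 - 0.25 * r)
    p$ly_tightening <- 1 - 0.5 * r
    return(do.call(condition_params, unclass(p)))
  }
  stop("unknown condition label: ", label, call. = FALSE)
}

#' Condition presets for the optogenetic (tetrode) study
#'
#' Parameters for the PV-silencing sessions in which 50% of trains are
#' delivered under light. Silencing acts through `opto_suppression` (PV
#' units), `disinhibition` (non-PV units), `opto_gamma_gain` (basal gamma
#' rises), and `opto_kappa_factor` (phase locking falls). The
#' mGluR2/3-agonist session (`"LY3"`) tightens the across-unit rate
#' distribution, strengthens the initial response, raises phase locking,
#' and lowers basal gamma.
#'
#' @param treatment `"vehicle"` or `"LY3"`.
#' @return A [condition_params()] object.
#' @export
tetrode_presets <- function(treatment = c("vehicle", "LY3")) {
  treatment <- match.arg(treatment)
  base <- condition_params(
    assr_kappa = 6, n_units = 40, pv_fraction = 0.15,
    opto_suppression = 0.1, disinhibition = 1.5,
    opto_gamma_gain = 1.8, opto_kappa_factor = 0.35)
  if (treatment == "vehicle") return(base)
  p <- unclass(base)
  p$ly_tightening <- 0.6
  p$in_gain <- 4.5
  p$assr_kappa <- 9
  p$basal_gamma_sd_uv <- 1.5
  do.call(condition_params, p)
}

#' @export
print.condition_params <- function(x, ...) {
  cat("<condition_params>\n")
  cat(sprintf("  ERP: n1 %g uV @ %g s, gating %g\n",
              x$n1_amp_uv, x$n1_latency_s, x$gating_g))
  cat(sprintf("  ASSR: amp %g uV, kappa %g, boost %g; basal gamma sd %g uV\n",
              x$assr_amp_uv, x$assr_kappa, x$initial_boost,
              x$basal_gamma_sd_uv))
  cat(sprintf("  noise: 1/f^%g, sd %g uV; units: n %d (PV %g), in %gx mp %gx\n",
              x$noise_alpha, x$noise_sd_uv, x$n_units, x$pv_fraction,
              x$in_gain, x$mp_gain))
  invisible(x)
}
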