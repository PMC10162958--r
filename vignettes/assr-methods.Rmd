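---
title: "Models and methods behind assrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind assrtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrtools)
```

`assrtools` analyzes two auditory paradigms used to probe cortical
excitation/inhibition balance in mice — double-click evoked potentials and
the 40 Hz auditory steady-state response (ASSR) — and simulates complete
sessions of both, with known ground truth, so that every metric can be
validated without recorded data. This vignette explains the generative
model, the analysis definitions, the defaults and why they were chosen,
and what the simulator does and does not capture.

## The measurement model

### Evoked potentials and gating

A double-click session presents `n` identical click pairs (default 300,
pair onsets 8 s apart, 0.5 s within a pair). The continuous EEG is epoched
around each click, baseline-corrected (mean over −100 to 0 ms), and
averaged per click position. The **n1** is the minimum of the averaged
waveform inside a 10–100 ms post-click search window; ties resolve to the
earliest sample. **Sensory gating** is the ratio of the second-click to
the first-click n1 amplitude: near 0 means the second response is
suppressed, near 1 means no gating. Whether gating should be a ratio or a
difference is a convention choice; the ratio is primary here and the
difference (S1 − S2) is reported alongside. The n1 is measured on the
trial-averaged waveform, not per trial, matching how averaged traces are
presented and avoiding single-sweep noise in the extremum.

### Time-frequency decomposition

All spectral quantities come from convolution with complex Morlet wavelets
— a Gaussian envelope carrying `n_cycles` cycles at each frequency,
truncated at ±3 envelope SDs and normalized to unit energy. The default
`n_cycles = 6` is a common compromise: at 40 Hz it gives a time resolution
(envelope SD) of ~24 ms and a frequency resolution of ~7 Hz. Samples
closer to an epoch edge than the wavelet half-width are flagged and
excluded from every window average, so edge ringing never contaminates a
metric.

Two power readouts are distinguished. **Total** power averages
single-trial power over trials (`mean |z_k|²`) and retains activity
regardless of its phase relation to the stimulus; **evoked** power is the
power of the trial-mean coefficient (`|mean z_k|²`) and retains only
phase-locked activity. Jensen's inequality guarantees evoked ≤ total
everywhere, which the test suite asserts on arbitrary inputs. Since
figure color scales in the source literature are arbitrary, only relative
and contrast claims are meaningful; powers are reported in µV² up to the
fixed wavelet normalization, with no dB conversion.

**Inter-trial coherence** is the mean resultant length of per-trial phase,
`ITC(f,t) = |N^{-1} Σ_k exp(i φ_k(f,t))|` — the phase-locking factor.
It is 1 under perfect locking and concentrates around
`√π / (2√N)` for fully random phases (the Rayleigh expectation), which
provides the null anchor used in the tests. Zero-magnitude coefficients
have no phase and are excluded pointwise with a logged count.

### Phase windows

ASSR responses are split into a **baseline** (−2 to 0 s), an **initial
response** (0–50 ms), and a **maintenance phase** (50–2000 ms) relative to
train onset; the same windows define the firing-rate phases for units.
**Basal gamma** is total-mode 30–80 Hz power in a −1.5 to −0.5 s window —
inside the baseline but at least one wavelet half-width clear of the epoch
edge and of stimulation onset.

### Single units

PSTHs pool spikes across trains after alignment, bin them (20 ms), and
divide by `n_trains × bin width`; the binned rates conserve the pooled
spike count exactly. Phase rates divide pooled counts by
`n_trains × window length`. Units with baseline rate below 0.1 Hz are
flagged: their phase ratios are numerically unstable and are excluded
from ratio summaries (a zero baseline flags the ratios undefined rather
than infinite). Opto-suppression is quantified by the symmetric index
`(r_opto − r_no)/(r_opto + r_no)` in [−1, 1]; units below −0.5 are called
putative PV+ interneurons. The threshold is a documented default — no
criterion is standard — and the index itself is always reported. No
spike-waveform cell typing is attempted.

### Inference

The cross-over EEG study is analyzed with a fixed-effects
`value ~ subject + treatment` least-squares model; condition adjusted
means and Wald t contrasts against the vehicle and the challenge
condition reproduce least-squares-means reporting. In a balanced complete
cross-over this fixed-effects model yields the same contrasts as a
random-subject model, so random-effect machinery is deliberately avoided.
Session order is not modeled as a covariate — only subject and condition.
No multiplicity correction is applied by default (Holm is available via
the `adjust` argument). For the tetrode study the replicate unit is the
electrode, and a two-way fixed-effects ANOVA with interaction tests the
optogenetic and pharmacological mains and their interaction; degenerate
all-equal inputs report F = 0, p = 1 rather than a 0/0.

## The synthetic-session generator

The continuous trace is a sum of four components, each with an explicit
knob in `condition_params()`:

1. **1/f background** (`noise_alpha = 1`, `noise_sd_uv = 8` µV), built by
   Hermitian spectral synthesis with random phases and rescaled to an
   exact sample SD.
2. **Basal gamma**: band-limited (30–80 Hz) Gaussian noise
   (`basal_gamma_sd_uv = 2` µV at vehicle).
3. **Click responses**: a deterministic template — Gaussian n1 trough with
   smaller positive flanks, trough exactly `−n1_amp_uv` (30 µV at
   vehicle) at `n1_latency_s` (40 ms) — added at each click; the second
   click of a pair is scaled by `gating_g` (0.5 at vehicle). The template
   support is 300 ms, so paired responses 0.5 s apart never overlap by
   construction.
4. **40 Hz entrainment**: one sinusoid per train with a per-trial phase
   drawn from a von Mises distribution of concentration `assr_kappa`
   (8 at vehicle) — the single knob controlling ITC — at amplitude
   `assr_amp_uv × initial_boost` for the first 50 ms and `assr_amp_uv`
   thereafter. This is a deliberate simplification relative to convolving
   click-wise impulse responses: a phase-jittered sinusoid is sufficient
   to drive every downstream metric (power, evoked/total split, ITC,
   phase windows), and trial-level jitter is the only jitter modeled.

Spike trains are inhomogeneous Poisson processes generated by thinning at
each unit's peak rate:
`λ(t) = λ_base · m_stim(t) · m_opto(t)`, with `m_stim = in_gain` (3) in
the first 50 ms, `mp_gain (1.5) × (1 + 0.3 sin(2π·40·t))` during
50–2000 ms, and 1 elsewhere; during opto-flagged trains `m_opto` is
`opto_suppression` (0.1) for PV+ units and `disinhibition` (1.5) for the
rest. Baseline rates are log-normal across units (median 5 Hz, log-SD
0.6); `ly_tightening` shrinks them linearly toward their mean, so a value
of 0.5 halves the across-unit SD exactly. 15% of units are flagged PV+ —
inside the 10–20% inhibitory complement of a cortical population that is
80–90% excitatory. Spike times are reported on a 40 kHz grid (0.025 ms),
matching standard acquisition resolution.

### Condition presets

The source studies report the *direction* of every effect but no numeric
effect sizes (results live in figure panels), so preset magnitudes are
package choices, fixed once:

| parameter | vehicle | MK-801 | PV silencing (opto trials) |
|---|---|---|---|
| n1 amplitude (µV) | 30 | 15 | — |
| gating ratio | 0.5 | 0.8 | — |
| basal gamma SD (µV) | 2 | 3.5 | ×1.8 |
| 40 Hz amplitude (µV) | 5 | 2.5 | — |
| von Mises κ | 8 | 2 | ×0.35 |

Co-treatment with the mGluR2/3 agonist moves every MK-801-affected
parameter back toward vehicle by the saturating fraction
`dose/(dose + 1)`, making rescue monotone in dose; the agonist alone
raises phase locking, lowers basal gamma, and tightens the unit rate
distribution. Although one reported dissociation is that 40 Hz power was
*not* rescued pharmacologically, the preset rescues all parameters
uniformly — the simpler preset table was preferred, and the dissociation
is not asserted anywhere in the tests. Optogenetic silencing acts through
PV suppression, disinhibition, the basal-gamma gain, and the κ factor;
the κ factor reproduces the reported ITC drop under PV silencing and is
the one place the opto model touches the continuous trace beyond gamma.

### What the simulator does not capture

No biophysics: no conductance-based dynamics, no spike waveforms, no
photocurrent kinetics, no volume conduction model (channels share the
signal and differ only in noise). Sample-level phase jitter, latency
jitter of the n1, drifting electrodes, movement artifacts, and
line noise are absent. Passing tests therefore demonstrate that the
*analysis* correctly recovers known ground truth of this generative
family and that effect directions propagate through the full pipeline —
not that real recordings satisfy the model.

## Numerical choices and edge cases

* Onsets are continuous seconds; sample alignment rounds to the nearest
  sample downstream.
* Wavelet grids: 1–100 Hz at 1 Hz is the fine default for maps; the
  session summaries use 30–80 Hz in 5 Hz steps (containing 40 Hz) to keep
  runtime low. The evoked-gamma rectangle is 30–80 Hz × 0–100 ms
  post-click; the rectangle location is a package default since the
  source shows it only graphically.
* A 50 ms initial window cannot be fully resolved by any admissible
  Morlet wavelet at 40 Hz (`n_cycles ≥ 3` implies a half-width ≥ 36 ms),
  so the measured initial/maintenance evoked-power ratio under a 2×
  amplitude boost is attenuated below the asymptotic 4; the tests verify
  the exact quadratic ratio on a resolvable plateau and the correct
  ordering on the 50 ms transient.
* Ties in the n1 search resolve to the earliest sample; a flat window
  returns amplitude 0 at the window start.
* Epoch rejection is monotone in the threshold; trials dropped at edges
  or by amplitude are counted by reason.
* The opto run-length-constrained assignment uses sequential sampling
  with a feasibility invariant (each remaining type must fit into
  `max_run`-sized blocks separated by the other type), so it never dead-
  ends; infeasible parameter combinations error out up front. With
  fraction 0 or 1 the run constraint is vacuous by convention.
* All randomness is scoped: every generator takes a `seed` and restores
  the caller's RNG state, making sessions bit-reproducible.

## Problem sizes used by the test suite

Full-scale protocols (300/600 trials, 19/8 subjects) are simulated where
the check is about exact protocol counts. Statistical checks use reduced
sizes chosen for comfortable margins: direction-of-effect checks run 100
seed pairs of 30-pair ERP and 20-train ASSR sessions (preset effect sizes
separate conditions by far more than the Monte-Carlo spread at these
counts); parameter recovery uses 100 seeded repeats; inference
calibration uses 400 null simulations at the study's real dimensions
(19 subjects × 4 conditions; 25 electrodes × 2 × 2). The pipeline default
(`pipeline_config()`) is likewise a scaled-down cohort and documents its
counts; set the trial and subject numbers back to the full protocol for
production-scale runs.

## Known limitations

* EDF import/export is not provided; the documented CSV dialect
  (`time_s` plus one column per channel) is the exchange format for
  continuous traces.
* The least-squares-means approximation is exact only for balanced
  complete cross-overs; unbalanced tables still fit, but contrasts then
  differ from a mixed-model analysis.
* Absolute spectral power depends on the wavelet normalization; compare
  powers only within a fixed grid and `n_cycles`.
* Unit populations are treated as independent across sessions; no
  unit-identity tracking across days is attempted.
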