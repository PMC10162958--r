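# assrtools

Analysis and simulation toolkit for mouse auditory electrophysiology
studies of cortical excitation/inhibition (E/I) balance. It covers the two
standard EEG/LFP paradigms used to probe early sensory processing —
double-click evoked potentials (n1 amplitude and sensory gating) and the
40 Hz auditory steady-state response (ASSR) — together with single-unit
firing analysis, and ships a synthetic-session generator that emulates a
systemic NMDA-receptor-antagonist challenge (MK-801), its rescue by an
mGluR2/3 agonist (LY379268), and local optogenetic silencing of
parvalbumin-positive (PV+) interneurons. Every analysis stage is therefore
testable end to end without any recorded data.

Intended users: preclinical electrophysiologists and methods developers
who need reproducible ERP/ASSR/spike metrics, or a ground-truthed
simulator to validate such metrics.

## What it computes

* **Protocols and designs** — double-click sessions (300 pairs, 8 s
  apart), 40 Hz click-train sessions (300 trains of 80 clicks over 2 s,
  10 s apart; 600-train variant with 50% of trains under light, in a
  pseudorandom sequence with bounded run lengths), randomized cross-over
  treatment designs.
* **ERP metrics** — epoching with baseline correction and artifact
  rejection; n1 amplitude and latency on the trial-averaged waveform;
  sensory gating as the S2/S1 n1 ratio (difference score also reported).
* **Time-frequency metrics** — complex Morlet decomposition (unit-energy
  wavelets, `n_cycles` = 6 default, edge flagging); inter-trial coherence
  as the mean resultant length of per-trial phase,
  `ITC(f,t) = |N^-1 Σ_k exp(i φ_k(f,t))|`; evoked vs total band power
  (power of the trial mean vs mean single-trial power); basal gamma
  (30–80 Hz, pre-stimulus); 40 Hz power and ITC split into the initial
  (0–50 ms) and maintenance (50–2000 ms) response phases.
* **Unit metrics** — PSTHs (20 ms bins), BL/In/MP phase rates and ratios,
  across-unit rate-distribution spread, and an opto-suppression index
  `(r_opto − r_no-opto)/(r_opto + r_no-opto)` for putative PV+
  classification.
* **Inference** — least-squares-means condition contrasts from a
  within-subject `value ~ subject + treatment` model, and a two-way
  optogenetics × drug ANOVA with interaction.
* **Simulator** — 1/f noise + band-limited basal gamma + ERP templates +
  phase-jittered (von Mises) 40 Hz entrainment for the continuous trace;
  inhomogeneous-Poisson spike trains via thinning with
  initial/maintenance gain, PV suppression, and disinhibition. Condition
  presets encode the reported directions of every MK-801, LY379268, and
  PV-silencing effect, with dose-dependent rescue.

## Worked example

Simulate one full-scale double-click session (300 pairs) and one ASSR
session (300 trains) per condition and compare vehicle against the NMDA
antagonist:

```r
library(assrtools)

sess  <- build_erp_protocol(300, iti_s = 8, pair_gap_s = 0.5)
rec_v <- synth_continuous(sess$protocol, sess$events, preset_params("vehicle"), seed = 101)
rec_m <- synth_continuous(sess$protocol, sess$events, preset_params("MK801"),   seed = 101)
rbind(vehicle = erp_session_metrics(rec_v, sess$events),
      MK801   = erp_session_metrics(rec_m, sess$events))
#>         n1_s1_uv n1_s2_uv ... gating_ratio
#> vehicle    -30.0    -15.7 ...        0.525
#> MK801      -14.9    -13.0 ...        0.868

assr <- build_assr_protocol(300, click_rate_hz = 40, train_dur_s = 2, iti_s = 10)
ra_v <- synth_continuous(assr$protocol, assr$events, preset_params("vehicle"), seed = 202)
ra_m <- synth_continuous(assr$protocol, assr$events, preset_params("MK801"),   seed = 202)
rbind(vehicle = assr_session_metrics(ra_v, assr$events),
      MK801   = assr_session_metrics(ra_m, assr$events))
#>         power40_in power40_mp ... itc40_mp basal_gamma_uv2
#> vehicle        981      472.1 ...    0.891              78
#> MK801          147       71.9 ...    0.474             148
```

Reading the numbers: under vehicle the averaged first-click n1 reaches
−30 µV and the second click is gated to about half that (ratio 0.53);
under MK-801 the n1 halves (−14.9 µV) and gating largely disappears
(ratio 0.87), while 40 Hz steady-state power and inter-trial coherence
collapse (ITC 0.89 → 0.47) and basal gamma roughly doubles — the
qualitative signature of NMDA-receptor hypofunction. `run_pipeline()`
wraps the same steps for a whole cross-over cohort plus the optogenetic
tetrode study and writes tidy CSVs, contrasts, and a run manifest.

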