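test_that("pink noise has the requested spectral slope and scale", {
  # alpha = 0 reduces to white noise: marginal normality and flat spectrum
  x <- pink_noise(10000, 0, 1, fs = 1000, seed = 4)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  ks <- suppressWarnings(ks.test(x / sd(x), "pnorm"))
  expect_gt(ks$p.value, 0.01)

  # alpha = 1: periodogram regression over 2-100 Hz recovers slope -1
  y <- pink_noise(10000, 1, 1, fs = 1000, seed = 4)
  P <- Mod(fft(y))^2
  f <- (1:5000) * 1000 / 10000
  sel <- f >= 2 & f <= 100
  slope <- unname(coef(lm(log(P[2:5001][sel]) ~ log(f[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.2)

  expect_identical(pink_noise(2, 1, 0, seed = 1), c(0, 0))
  expect_identical(pink_noise(512, 1, 3, seed = 9),
                   pink_noise(512, 1, 3, seed = 9))
})

test_that("evoked-potential template has its trough where specified", {
  w <- erp_template(30, 0.04, 1000)
  expect_equal(min(w), -30)
  expect_equal(attr(w, "times")[which.min(w)], 0.04)

  expect_true(all(erp_template(0, 0.04, 1000) == 0))

  w2 <- erp_template(30, 0.04, 2000)
  expect_equal(min(w2), -30)
  expect_equal(which.min(w2), 81) # sample 80 at 2 kHz, 1-based index
  expect_error(erp_template(30, -0.01), "latency")
})

test_that("identity gating makes the two click responses identical", {
  sess <- build_erp_protocol(5)
  p <- silent_params(gating_g = 1)
  rec <- synth_continuous(sess$protocol, sess$events, p, seed = 1)
  a1 <- average_erp(extract_epochs(rec, sess$events, "click1", 0.1, 0.3),
                    baseline_correct = FALSE)
  a2 <- average_erp(extract_epochs(rec, sess$events, "click2", 0.1, 0.3),
                    baseline_correct = FALSE)
  expect_equal(as.numeric(a1), as.numeric(a2), tolerance = 1e-12)
})

test_that("the simulator is bit-reproducible and ignores unused knobs at zero amplitude", {
  sess <- build_assr_protocol(6)
  p <- condition_params()
  r1 <- synth_continuous(sess$protocol, sess$events, p, seed = 12)
  r2 <- synth_continuous(sess$protocol, sess$events, p, seed = 12)
  expect_identical(r1$data, r2$data)

  # with a zero entrained amplitude the trace equals the noise components
  # regardless of the phase-locking parameter
  pa <- condition_params(assr_amp_uv = 0, assr_kappa = 1, n1_amp_uv = 0)
  pb <- condition_params(assr_amp_uv = 0, assr_kappa = 50, n1_amp_uv = 0)
  ra <- synth_continuous(sess$protocol, sess$events, pa, seed = 3)
  rb <- synth_continuous(sess$protocol, sess$events, pb, seed = 3)
  expect_identical(ra$data, rb$data)
})

test_that("scaling the entrained amplitude scales evoked 40 Hz power quadratically", {
  sess <- build_assr_protocol(4)
  tf_for <- function(amp) {
    p <- silent_params(n1_amp_uv = 0, assr_kappa = Inf, assr_amp_uv = amp)
    rec <- synth_continuous(sess$protocol, sess$events, p, seed = 1)
    ep <- extract_epochs(rec, sess$events, "train_start", 2.5, 2.3,
                         baseline_window = c(-2, 0))
    morlet_tf(ep, c(35, 40, 45))
  }
  p1 <- band_power(tf_for(3), c(40, 40), c(0.3, 1.7), "evoked")
  p2 <- band_power(tf_for(6), c(40, 40), c(0.3, 1.7), "evoked")
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})

test_that("stronger phase locking raises inter-trial coherence", {
  sess <- build_assr_protocol(12)
  itc_for <- function(kappa, seed) {
    p <- condition_params(assr_kappa = kappa, n1_amp_uv = 0)
    rec <- synth_continuous(sess$protocol, sess$events, p, seed = seed)
    assr_session_metrics(rec, sess$events, freqs_hz = c(35, 40, 45))$itc40_mp
  }
  m <- sapply(c(0.5, 3, 20), function(k)
    mean(sapply(1:6, function(s) itc_for(k, 40 * s))))
  expect_true(all(diff(m) > 0))
})

test_that("spike trains realize the programmed Poisson intensities", {
  # stationary unit: empirical rate within 3 SE of the base rate
  sess <- build_assr_protocol(2)
  p <- condition_params(n_units = 1, pv_fraction = 0,
                        rate_meanlog = log(10), rate_sdlog = 0,
                        in_gain = 1, mp_gain = 1, mp_mod_depth = 0)
  sp <- synth_spike_trains(sess$protocol, sess$events, c(FALSE, FALSE), p,
                           seed = 8, span_s = 1000)
  rate <- nrow(sp$spikes) / 1000
  expect_lt(abs(rate - 10), 3 * sqrt(10 / 1000))

  # fully suppressed PV unit emits nothing inside opto trains
  p2 <- condition_params(n_units = 3, pv_fraction = 1, opto_suppression = 0,
                         rate_meanlog = log(20), rate_sdlog = 0)
  sess2 <- build_assr_protocol(10)
  sp2 <- synth_spike_trains(sess2$protocol, sess2$events, rep(TRUE, 10), p2,
                            seed = 2)
  rel <- outer(sp2$spikes$spike_time_s, sp2$onsets, "-")
  expect_false(any(rel >= 0 & rel < 2))

  # PV head-count is the rounded fraction
  p3 <- condition_params(n_units = 40, pv_fraction = 0.15)
  sp3 <- synth_spike_trains(sess2$protocol, sess2$events, rep(FALSE, 10), p3,
                            seed = 3)
  expect_equal(sum(sp3$units$pv), 6)

  expect_identical(
    synth_spike_trains(sess2$protocol, sess2$events, rep(FALSE, 10), p3,
                       seed = 5)$spikes,
    synth_spike_trains(sess2$protocol, sess2$events, rep(FALSE, 10), p3,
                       seed = 5)$spikes)
})

test_that("rate tightening shrinks the across-unit spread exactly", {
  sess <- build_assr_protocol(4)
  base <- condition_params(n_units = 30)
  tight <- condition_params(n_units = 30, ly_tightening = 0.5)
  u1 <- synth_spike_trains(sess$protocol, sess$events, rep(FALSE, 4), base,
                           seed = 21)$units$base_rate_hz
  u2 <- synth_spike_trains(sess$protocol, sess$events, rep(FALSE, 4), tight,
                           seed = 21)$units$base_rate_hz
  expect_equal(sd(u2) / sd(u1), 0.5, tolerance = 1e-12)
  expect_equal(mean(u2), mean(u1), tolerance = 1e-12)
})
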