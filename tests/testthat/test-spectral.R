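sine_epochs <- function(freq, amp = 1, n_trials = 1, dur = 2, fs = 1000,
                        phase = 0) {
  tt <- (seq_len(dur * fs) - 1) / fs
  make_epochs(matrix(rep(amp * sin(2 * pi * freq * tt + phase),
                         each = n_trials), n_trials), fs = fs)
}

test_that("wavelet power localizes a pure tone at its frequency", {
  ep <- sine_epochs(40)
  tf <- morlet_tf(ep, seq(30, 80, by = 5))
  pw <- Mod(tf[1, , ])^2
  interior <- which(!apply(attr(tf, "edge"), 2, any))
  expect_true(all(apply(pw[, interior], 2, which.max) ==
                    which(attr(tf, "freqs_hz") == 40)))

  zero <- morlet_tf(make_epochs(matrix(0, 2, 1000)), c(20, 40))
  expect_true(all(Mod(zero) == 0))

  expect_error(morlet_tf(ep, c(40, 600)), "Nyquist")
})

test_that("doubling a tone's amplitude quadruples interior power", {
  tf1 <- morlet_tf(sine_epochs(40, amp = 1), c(40))
  tf2 <- morlet_tf(sine_epochs(40, amp = 2), c(40))
  r <- band_power(tf2, c(40, 40), c(0.5, 1.5), "total") /
    band_power(tf1, c(40, 40), c(0.5, 1.5), "total")
  expect_equal(r, 4, tolerance = 1e-6)
})

test_that("inter-trial coherence matches its closed-form anchors", {
  # identical phases across trials -> 1 everywhere
  co <- array(complex(modulus = runif(5 * 3 * 7, 0.5, 2), argument = 1.1),
              c(5, 3, 7))
  expect_true(all(abs(itc(tf_map(co, 1:3, 1:7))$itc - 1) < 1e-12))

  # two opposite phases -> 0
  co2 <- array(c(complex(argument = 0.3, modulus = 1),
                 complex(argument = 0.3 + pi, modulus = 1)), c(2, 1, 1))
  expect_lt(itc(tf_map(co2, 1, 1))$itc[1, 1], 1e-12)

  # uniform phases -> Rayleigh expectation sqrt(pi)/(2 sqrt(N))
  set.seed(5)
  for (N in c(10, 100, 300)) {
    co3 <- array(complex(modulus = 1, argument = runif(N * 20 * 40, -pi, pi)),
                 c(N, 20, 40))
    r <- itc(tf_map(co3, 1:20, 1:40))$itc
    expect_equal(mean(r), sqrt(pi) / (2 * sqrt(N)), tolerance = 0.15)
    expect_lt(abs(mean(r) - sqrt(pi) / (2 * sqrt(N))), 0.02)
  }
})

test_that("ITC stays in [0,1], ignores positive rescaling, drops zero coefficients", {
  set.seed(6)
  for (i in 1:5) {
    co <- array(complex(real = rnorm(8 * 4 * 6), imaginary = rnorm(8 * 4 * 6)),
                c(8, 4, 6))
    r <- itc(tf_map(co, 1:4, 1:6))$itc
    expect_true(all(r >= 0 & r <= 1 + 1e-12))
    scaled <- co * array(rep(runif(8, 0.1, 5), 4 * 6), c(8, 4, 6))
    expect_equal(itc(tf_map(scaled, 1:4, 1:6))$itc, r, tolerance = 1e-12)
  }
  co <- array(complex(modulus = 1, argument = 0.2), c(3, 1, 1))
  co[2, 1, 1] <- 0
  res <- itc(tf_map(co, 1, 1))
  expect_equal(res$n_excluded[1, 1], 1)
  expect_equal(res$itc[1, 1], 1)
})

test_that("evoked power never exceeds total power", {
  expect_jensen <- function(co) {
    tfm <- tf_map(co, 1:dim(co)[2], seq_len(dim(co)[3]))
    expect_lte(band_power(tfm, c(1, dim(co)[2]), c(1, dim(co)[3]), "evoked"),
               band_power(tfm, c(1, dim(co)[2]), c(1, dim(co)[3]), "total") +
                 1e-12)
  }
  set.seed(7)
  for (i in 1:10) {
    co <- array(complex(real = rnorm(12 * 5 * 9), imaginary = rnorm(12 * 5 * 9)),
                c(12, 5, 9))
    expect_jensen(co)
  }

  # N = 1: the two modes coincide exactly
  co1 <- array(complex(real = rnorm(40), imaginary = rnorm(40)), c(1, 5, 8))
  tf1 <- tf_map(co1, 1:5, 1:8)
  expect_equal(band_power(tf1, c(1, 5), c(1, 8), "evoked"),
               band_power(tf1, c(1, 5), c(1, 8), "total"))

  # random independent phases: evoked collapses far below total
  set.seed(8)
  coN <- array(complex(modulus = 1, argument = runif(300 * 2 * 10, -pi, pi)),
               c(300, 2, 10))
  tfN <- tf_map(coN, 1:2, 1:10)
  expect_lt(band_power(tfN, c(1, 2), c(1, 10), "evoked") /
              band_power(tfN, c(1, 2), c(1, 10), "total"), 0.1)

  zero <- tf_map(array(0i, c(2, 2, 2)), 1:2, 1:2)
  expect_equal(band_power(zero, c(1, 2), c(1, 2), "total"), 0)
  expect_equal(band_power(zero, c(1, 2), c(1, 2), "evoked"), 0)
})

test_that("basal gamma power scales with the simulated gamma variance", {
  sess <- build_assr_protocol(8)
  bg_for <- function(gsd) {
    p <- condition_params(basal_gamma_sd_uv = gsd, noise_sd_uv = 1,
                          n1_amp_uv = 0, assr_amp_uv = 0)
    rec <- synth_continuous(sess$protocol, sess$events, p, seed = 31)
    ep <- extract_epochs(rec, sess$events, "train_start", 2.5, 0.5,
                         baseline_window = c(-2, 0))
    basal_gamma(ep)
  }
  expect_equal(bg_for(6) / bg_for(3), 4, tolerance = 0.1)

  # out-of-band rejection: a 100 Hz tone leaks < 1% of an in-band tone
  # (8 cycles: sharp enough in frequency to keep 100 Hz > 20 dB down)
  tt <- (seq_len(3000) - 1) / 1000
  tone_ep <- function(f) make_epochs(matrix(sin(2 * pi * f * tt), 1),
                                     pre_s = 2.5)
  expect_lt(basal_gamma(tone_ep(100), n_cycles = 8) /
              basal_gamma(tone_ep(50), n_cycles = 8), 0.01)

  expect_identical(bg_for(3), bg_for(3)) # determinism
})

test_that("phase-split steady-state metrics behave at their anchors", {
  expect_error(phase_windows(bl = c(-2, 0.1)), "non-overlapping")
  w <- phase_windows()
  expect_equal(diff(w$bl), 2)
  expect_equal(diff(w$initial), 0.05)
  expect_equal(w$maintenance, c(0.05, 2))

  # perfect locking, noiseless: unit coherence in both phases
  sess <- build_assr_protocol(4)
  p <- silent_params(n1_amp_uv = 0, assr_kappa = Inf)
  rec <- synth_continuous(sess$protocol, sess$events, p, seed = 1)
  ep <- extract_epochs(rec, sess$events, "train_start", 2.5, 2.3,
                       baseline_window = c(-2, 0))
  m <- assr_metrics(morlet_tf(ep, c(35, 40, 45)))
  expect_equal(m$itc40_in, 1, tolerance = 1e-9)
  expect_equal(m$itc40_mp, 1, tolerance = 1e-9)
  expect_gt(m$power40_in, m$power40_mp) # the initial transient is stronger

  # a resolvable amplitude plateau recovers the squared amplitude ratio:
  # 2 s at amplitude 2A then 2 s at A, windows away from the step
  fs <- 1000
  tt <- (seq_len(4 * fs) - 1) / fs
  x <- ifelse(tt < 2, 2, 1) * sin(2 * pi * 40 * tt)
  ep2 <- make_epochs(matrix(rep(x, each = 3), 3), fs = fs)
  tf2 <- morlet_tf(ep2, c(40))
  r <- band_power(tf2, c(40, 40), c(0.5, 1.5), "evoked") /
    band_power(tf2, c(40, 40), c(2.5, 3.5), "evoked")
  expect_equal(r, 4, tolerance = 0.05)
})
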