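test_that("epoch extraction counts, rejects, and aligns correctly", {
  sess <- build_erp_protocol(20)
  rec <- synth_continuous(sess$protocol, sess$events, condition_params(),
                          seed = 2)
  ep <- extract_epochs(rec, sess$events, "click1", 0.2, 0.3)
  expect_equal(n_epochs(ep), 20)
  expect_equal(attr(ep, "rejections"), c(edge = 0L, amplitude = 0L))
  expect_equal(length(attr(ep, "times")), 500)
  expect_equal(attr(ep, "times")[1], -0.2)

  # constant-zero recording: all-zero epochs, nothing rejected
  zrec <- make_recording(matrix(0, 20000, 1), start_s = -1)
  zep <- extract_epochs(zrec, sess$events[sess$events$trial_id <= 3, ],
                        "click1", 0.2, 0.3, reject_uv = 100)
  expect_equal(n_epochs(zep), 3)
  expect_true(all(zep == 0))
  expect_equal(sum(attr(zep, "rejections")), 0)

  # event too close to the recording edge
  ev1 <- data.frame(onset_s = 0.1, event_type = "click1", trial_id = 1,
                    opto = FALSE)
  short <- make_recording(matrix(0, 2000, 1), start_s = 0)
  expect_error(extract_epochs(short, ev1, "click1", 0.5, 0.3,
                              baseline_window = c(-0.1, 0)),
               "edge")
})

test_that("epoch rejection is monotone in the threshold", {
  set.seed(3)
  sess <- build_erp_protocol(30)
  rec <- make_recording(matrix(rnorm(300000, sd = 30), ncol = 1),
                        start_s = -2)
  counts <- sapply(c(Inf, 120, 90, 60, 45), function(th)
    tryCatch(n_epochs(extract_epochs(rec, sess$events, "click1", 0.2, 0.3,
                                     reject_uv = th)),
             error = function(e) 0L))
  expect_true(all(diff(counts) <= 0))
})

test_that("trial averaging is exact, linear, and respects the baseline", {
  w <- sin(seq(0, 4 * pi, length.out = 200))
  ep_same <- make_epochs(rbind(w, w, w))
  expect_equal(as.numeric(average_erp(ep_same, baseline_correct = FALSE)), w)

  ep_cancel <- make_epochs(rbind(w, -w))
  expect_equal(as.numeric(average_erp(ep_cancel, baseline_correct = FALSE)),
               rep(0, 200))

  # linearity
  set.seed(7)
  m <- matrix(rnorm(600), 3)
  expect_equal(as.numeric(average_erp(make_epochs(3.5 * m),
                                      baseline_correct = FALSE)),
               3.5 * as.numeric(average_erp(make_epochs(m),
                                            baseline_correct = FALSE)))

  # CLT bound: 300 noisy copies of a template recover it pointwise
  set.seed(8)
  tmpl <- as.numeric(erp_template(30, 0.04, 1000))
  noise_sd <- 5
  mm <- matrix(rep(tmpl, each = 300), 300) +
    matrix(rnorm(300 * length(tmpl), sd = noise_sd), 300)
  avg <- average_erp(make_epochs(mm), baseline_correct = FALSE)
  expect_true(all(abs(as.numeric(avg) - tmpl) <
                    4 * noise_sd / sqrt(300)))
})

test_that("n1 measurement finds the trough, with earliest-tie rule", {
  w <- erp_template(30, 0.04, 1000)
  m <- measure_n1(w, 0.01, 0.1)
  expect_equal(m$amplitude_uv, -30)
  expect_equal(m$latency_s, 0.04)

  flat <- make_epochs(matrix(0, 2, 300))
  mf <- measure_n1(average_erp(flat, baseline_correct = FALSE), 0.01, 0.1)
  expect_equal(mf$amplitude_uv, 0)
  expect_equal(mf$latency_s, 0.01) # degenerate tie resolves to window start

  # Monte-Carlo: 300-trial averages of template + unit white noise stay
  # within 0.2 uV of the true amplitude across 100 repeats
  tmpl <- as.numeric(erp_template(30, 0.04, 1000))
  set.seed(9)
  amps <- replicate(100, {
    avg <- tmpl + rnorm(length(tmpl), sd = 1 / sqrt(300))
    aw <- make_epochs(matrix(avg, 1))
    measure_n1(average_erp(aw, baseline_correct = FALSE), 0.01, 0.1)$amplitude_uv
  })
  expect_true(all(abs(amps + 30) < 0.2))
})

test_that("gating ratio arithmetic and recovery from simulation", {
  expect_equal(gating_ratio(-10, -5), 0.5)
  expect_equal(gating_ratio(-10, -10), 1)
  expect_error(gating_ratio(0, -5), "undefined-gating")

  # noiseless: measured S2/S1 equals the programmed factor exactly
  sess <- build_erp_protocol(6)
  p0 <- silent_params(gating_g = 0.4)
  rec0 <- synth_continuous(sess$protocol, sess$events, p0, seed = 1)
  m0 <- erp_session_metrics(rec0, sess$events)
  expect_equal(m0$gating_ratio, 0.4, tolerance = 1e-9)

  # low noise: recovered within 0.05
  p <- condition_params(gating_g = 0.4, noise_sd_uv = 2,
                        basal_gamma_sd_uv = 0.5)
  sess2 <- build_erp_protocol(30)
  rec <- synth_continuous(sess2$protocol, sess2$events, p, seed = 14)
  m <- erp_session_metrics(rec, sess2$events)
  expect_equal(m$gating_ratio, 0.4, tolerance = 0.05)
})
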