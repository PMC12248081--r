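# Detector contracts: threshold formulas, the dual-criterion rule,
# equivalence with a naive per-sample scan, monotonicity, and features.

test_that("channel thresholds follow the median / population-SD formulas", {
  th <- compute_channel_thresholds(c(1, 2, 3, 4, 5))
  expect_equal(th$thresh, 3)
  expect_equal(th$sigma, sqrt(2))
  expect_equal(th$thresh2, 3 + sqrt(2))

  const <- compute_channel_thresholds(rep(4.2, 50))
  expect_equal(c(const$sigma, const$thresh, const$thresh2), c(0, 4.2, 4.2))

  # independent per channel
  m <- cbind(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  th2 <- compute_channel_thresholds(m)
  expect_equal(th2$thresh, c(3, 30))
  expect_equal(th2$sigma, c(sqrt(2), 10 * sqrt(2)))
  expect_error(compute_channel_thresholds(matrix(NA_real_, 5, 1)), "NaN")
})

test_that("duration and max criteria both gate detection", {
  fs <- 1000
  base <- rep(0, 1000)
  # 90 ms above thresh with a huge max: too short
  e1 <- base; e1[101:190] <- 10
  expect_equal(nrow(detect_channel_bursts(e1, 1, 2, fs)), 0)
  # 150 ms run whose max stays below thresh2: rejected
  e2 <- base; e2[101:250] <- 1.5
  expect_equal(nrow(detect_channel_bursts(e2, 1, 2, fs)), 0)
  # 150 ms run with max above thresh2: kept, exact span
  e3 <- e2; e3[150] <- 3
  ev <- detect_channel_bursts(e3, 1, 2, fs)
  expect_equal(ev$start_sample, 101)
  expect_equal(ev$end_sample, 251)
  expect_equal(ev$end_s - ev$start_s, 0.150)
  # exactly 100 ms is kept ("at least")
  e4 <- base; e4[101:200] <- 3
  expect_equal(nrow(detect_channel_bursts(e4, 1, 2, fs)), 1)
  expect_error(detect_channel_bursts(e4, 1, 2, -1), "positive")
})

test_that("detector equals the naive per-sample scan on random envelopes", {
  set.seed(11)
  fs <- 250
  for (i in 1:40) {
    env <- abs(stats::rnorm(600)) + 2 * (stats::runif(600) < 0.05)
    env <- as.numeric(stats::filter(env, rep(1 / 8, 8), sides = 2))
    env[is.na(env)] <- 0
    th <- compute_channel_thresholds(as.numeric(env))
    got <- detect_channel_bursts(env, th$thresh, th$thresh2, fs)
    want <- naive_burst_scan(env, th$thresh, th$thresh2, fs)
    expect_equal(got$start_sample, want$start_sample)
    expect_equal(got$end_sample, want$end_sample)
  }
})

test_that("raising thresh2 never adds events; lowering min_dur never removes", {
  set.seed(12)
  fs <- 200
  for (i in 1:10) {
    env <- abs(stats::rnorm(500, sd = 1)) + 3 * (stats::runif(500) < 0.02)
    th <- compute_channel_thresholds(as.numeric(env))
    ev <- detect_channel_bursts(env, th$thresh, th$thresh2, fs)
    ev_hi <- detect_channel_bursts(env, th$thresh, th$thresh2 * 1.5, fs)
    expect_lte(nrow(ev_hi), nrow(ev))
    expect_true(all(ev_hi$start_sample %in% ev$start_sample))
    ev_short <- detect_channel_bursts(env, th$thresh, th$thresh2, fs,
                                      min_dur = 0.05)
    expect_true(all(ev$start_sample %in% ev_short$start_sample))
  }
})

test_that("burst features: normalized amplitude, duration, tone frequency", {
  fs <- 1000
  # mean envelope = thresh + sigma  =>  norm amplitude exactly 1
  env <- rep(2.5, 500)                 # thresh = 1.5, sigma = 1
  ph <- rep(0, 500)
  f <- compute_burst_features(101, 351, env, ph, thresh = 1.5, sigma = 1,
                              fs = fs)
  expect_equal(f$norm_amplitude, 1.0)
  expect_equal(f$duration_s, 0.25)
  # 20 Hz tone: mean instantaneous frequency within 0.5 Hz
  t <- (0:4999) / fs
  z <- analytic_signal(sin(2 * pi * 20 * t))
  f2 <- compute_burst_features(1000, 3000, Mod(z), Arg(z), 0, 1, fs)
  expect_equal(f2$mean_freq_hz, 20, tolerance = 0.5)
  expect_warning(
    compute_burst_features(101, 351, env, ph, 1.5, 0, fs), "sigma")
})

test_that("detect_bursts_all matches per-channel detection plus features", {
  set.seed(13)
  fs <- 200
  n <- 800
  amp <- matrix(abs(stats::rnorm(n * 3)), n, 3)
  amp[200:260, 2] <- amp[200:260, 2] + 4
  ph <- matrix(stats::runif(n * 3, -pi, pi), n, 3)
  ab <- structure(list(amplitude = amp, phase = ph, fs = fs,
                       band = c(15, 35), order = 3, edge_samples = 10),
                  class = "analytic_beta")
  res <- detect_bursts_all(ab)
  th <- compute_channel_thresholds(amp)
  for (j in 1:3) {
    ref <- detect_channel_bursts(amp[, j], th$thresh[j], th$thresh2[j], fs)
    expect_equal(res$events$start_sample[res$events$channel == j],
                 ref$start_sample)
  }
  # feature values agree with the one-event reference computation
  if (nrow(res$events)) {
    e1 <- res$events[1, ]
    ref_f <- compute_burst_features(e1$start_sample, e1$end_sample,
                                    amp[, e1$channel], ph[, e1$channel],
                                    th$thresh[e1$channel],
                                    th$sigma[e1$channel], fs)
    expect_equal(e1$norm_amplitude, ref_f$norm_amplitude)
    expect_equal(e1$mean_freq_hz, ref_f$mean_freq_hz)
  }
})
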