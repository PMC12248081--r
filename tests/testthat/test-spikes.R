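# Spiking analyses: SNR, epoch statistics, burst conditioning, phase
# entrainment, and the linear population-dynamics model.

test_that("waveform SNR follows the peak-trough / tail-SD formula", {
  expect_equal(unit_snr(rep(1, 20)), 0)
  # constructed: tail SD 1 around zero, peak - trough = 4
  tail_noise <- c(rep(-1, 8), rep(1, 8))   # SD = 1 (sample)
  wf <- c(tail_noise[1:8], -2, 2, tail_noise[9:16])
  snr <- unit_snr(wf, exclude = 9:10)
  expect_equal(snr, 4 / stats::sd(tail_noise))
  # random waveforms: equals an independent two-pass reference
  set.seed(41)
  for (i in 1:10) {
    w <- stats::rnorm(30)
    excl <- 10:20
    ref <- (max(w) - min(w)) / stats::sd(w[-excl])
    expect_equal(unit_snr(w, exclude = excl), ref)
  }
  expect_error(unit_snr(c(1, 2, 3), exclude = 1:3), "covers all")
})

test_that("unit inclusion gates on SNR > 3 and rate > 0.5 Hz", {
  wf_good <- c(rep(0.01, 10), -3, 3, rep(-0.01, 10))
  wf_flat <- rep(0.5, 22)
  spikes <- list(unit1 = seq(0, 99, by = 0.5),   # 2 Hz
                 unit2 = c(1, 2, 3),             # 0.03 Hz
                 unit3 = seq(0, 99, by = 0.5))
  waveforms <- list(mean = cbind(wf_good, wf_good, wf_flat))
  inc <- unit_inclusion(spikes, waveforms, 100)
  expect_equal(inc$included, c(TRUE, FALSE, FALSE))
})

test_that("epoch firing stats: exact bins, empty trains, Poisson recovery", {
  ep <- data.frame(start = 0, end = 1)
  # one spike in every 10 ms bin: 100 Hz, variability 0
  st <- epoch_firing_stats(seq(0.005, 0.995, by = 0.01), ep)
  expect_equal(st$mean_rate, 100)
  expect_equal(st$variability, 0)
  # no spikes: 0 / 0
  st0 <- epoch_firing_stats(numeric(0), ep)
  expect_equal(st0$mean_rate, 0)
  expect_equal(st0$variability, 0)
  # epoch shorter than a bin is skipped with a warning
  expect_warning(epoch_firing_stats(1:3, data.frame(start = 0, end = 0.005)),
                 "skipped")
  # Poisson spikes at 30 Hz over many trials recover the rate
  set.seed(42)
  eps <- data.frame(start = seq(0, 199, by = 2), end = seq(1, 200, by = 2))
  spk <- sort(stats::runif(30 * 200, 0, 200))
  stp <- epoch_firing_stats(spk, eps)
  expect_equal(stp$mean_rate, 30, tolerance = 0.1 * 30)
})

test_that("burst-conditioned firing reduces to epoch stats when labels are 0", {
  set.seed(43)
  fs <- 100
  labels <- integer(1000)      # 10 s, all no-burst
  ep <- data.frame(start = c(1, 4), end = c(3, 6))
  spk <- sort(stats::runif(100, 0, 10))
  bc <- burst_conditioned_firing(spk, labels, fs, ep)
  st <- epoch_firing_stats(spk, ep)
  expect_equal(bc$mean_rate[bc$condition == "none"], st$mean_rate)
  expect_true(is.na(bc$mean_rate[bc$condition == "local"]))
  expect_true(is.na(bc$mean_rate[bc$condition == "global"]))
})

test_that("resultant length: coherent limit, symmetric cancellation, Bessel ratio", {
  expect_equal(resultant_length(rep(1.3, 50)), 1)
  expect_equal(resultant_length(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  expect_true(is.na(resultant_length(numeric(0))))
  set.seed(44)
  r <- resultant_length(rvonmises(10000, 0, 1))
  expect_equal(r, besselI(1, 1) / besselI(1, 0), tolerance = 0.012)
})

test_that("phase entrainment flags zero-spike pairs and detects locking", {
  fs <- 1000
  n <- 20000
  t <- (seq_len(n) - 1) / fs
  phase <- matrix(Arg(exp(1i * 2 * pi * 20 * t)), ncol = 1)
  events <- data.frame(start_s = seq(1, 18, by = 1), category = "global")
  events$end_s <- events$start_s + 0.5
  # a unit spiking exactly at phase 0 of the 20 Hz cycle inside events
  locked <- unlist(lapply(seq_len(nrow(events)), function(i)
    seq(events$start_s[i], events$end_s[i] - 0.05, by = 0.05)))
  silent <- numeric(0)
  res <- phase_entrainment(list(locked = locked, silent = silent),
                           phase, fs, events, n_shuffles = 100, seed = 3)
  expect_equal(res$n_spikes[res$unit == "silent"], 0L)
  expect_true(is.na(res$r[res$unit == "silent"]))
  lr <- res[res$unit == "locked", ]
  expect_gt(lr$r, 0.95)
  expect_true(lr$significant)
  expect_gt(lr$z, 3)
})

test_that("entrainment-rate association filters units without significant channels", {
  entrain <- data.frame(unit = c("u1", "u1", "u2"), channel = c(1, 2, 1),
                        n_spikes = 10, r = 0.5, shuffle_mean = 0.2,
                        shuffle_sd = 0.05, z = c(4, 6, 1),
                        significant = c(TRUE, TRUE, FALSE))
  deltas <- data.frame(unit = c("u1", "u2"), delta_rate = c(-2, 1),
                       delta_variability = c(-1, 0.5))
  out <- entrainment_rate_association(entrain, deltas)
  expect_equal(out$table$unit, "u1")
  expect_equal(out$table$median_z, 5)
  expect_null(out$fit_rate)           # < 3 units: no regression
})

test_that("dynamics model recovers a noiseless linear system exactly", {
  set.seed(45)
  u <- 5
  A <- matrix(stats::rnorm(u * u, sd = 0.3), u, u)
  A <- A / (1.2 * max(Mod(eigen(A)$values)))
  trials <- lapply(1:6, function(i) {
    x <- matrix(0, 40, u)
    x[1, ] <- stats::rnorm(u)
    for (t in 2:40) x[t, ] <- A %*% x[t - 1, ]
    x
  })
  mod <- fit_dynamics_model(trials, train = 1:4)
  expect_lt(max(abs(mod$A - A)), 1e-8)
  expect_equal(dynamics_r2(mod, trials, 5:6), 1, tolerance = 1e-10)
})

test_that("dynamics fit is invariant to unit ordering", {
  set.seed(46)
  u <- 4
  trials <- lapply(1:5, function(i) matrix(stats::rnorm(30 * u), 30, u))
  mod <- fit_dynamics_model(trials, 1:3)
  perm <- c(3, 1, 4, 2)
  mod_p <- fit_dynamics_model(lapply(trials, function(m) m[, perm]), 1:3)
  expect_equal(mod_p$A, mod$A[perm, perm], tolerance = 1e-10)
  r2 <- dynamics_r2(mod, trials, 4:5)
  r2p <- dynamics_r2(mod_p, lapply(trials, function(m) m[, perm]), 4:5)
  expect_equal(r2, r2p, tolerance = 1e-10)
})

test_that("category predictability: identity gives 1, category mean gives 0", {
  set.seed(47)
  truth <- list(matrix(stats::rnorm(40), 20, 2))
  cond <- list(rep(c(0L, 2L), 10))
  perfect <- list(truth[[1]][-1, , drop = FALSE])
  r2 <- category_predictability(truth, perfect, cond)
  expect_equal(r2$r2[r2$category == "none"], 1)
  expect_equal(r2$r2[r2$category == "global"], 1)
  expect_true(is.na(r2$r2[r2$category == "local"]))
  expect_equal(r2$n_bins[r2$category == "local"], 0)
  # prediction = per-category mean of the true bins -> R2 = 0
  tr <- truth[[1]][-1, , drop = FALSE]
  cd <- cond[[1]][-1]
  pred <- tr
  for (k in c(0L, 2L)) pred[cd == k, ] <- mean(tr[cd == k, ])
  r20 <- category_predictability(truth, list(pred), cond)
  expect_equal(r20$r2[r20$category == "none"], 0, tolerance = 1e-12)
  expect_equal(r20$r2[r20$category == "global"], 0, tolerance = 1e-12)
})

test_that("dynamics subsample honors minimum availability", {
  trials <- lapply(1:5, function(i) matrix(stats::rnorm(60), 20, 3))
  expect_error(dynamics_subsample(trials, n_trials = 5, n_units = 3),
               "fewer")
  res <- dynamics_subsample(trials, n_trials = 3, n_units = 2, n_reps = 5,
                            seed = 1)
  expect_equal(nrow(res), 5)
})
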