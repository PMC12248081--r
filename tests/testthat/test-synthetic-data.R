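# Generator contracts: determinism, event bookkeeping, injection physics,
# spike-phase coupling and kinematics ground truth.

small_cfg <- function(...) {
  args <- list(session_duration = 20, n_cortical_channels = 16,
               n_subcortical_channels = 8, n_units = 4, seed = 42)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(synth_config, args)
}

test_that("identical seeds give bit-identical sessions", {
  a <- generate_session(small_cfg())
  b <- generate_session(small_cfg())
  expect_identical(a$bundle$lfp_cortex, b$bundle$lfp_cortex)
  expect_identical(a$bundle$spikes, b$bundle$spikes)
  expect_identical(a$bundle$kinematics, b$bundle$kinematics)
  expect_identical(a$truth$burst_events$start_s, b$truth$burst_events$start_s)
})

test_that("zero event rates give an empty ground-truth event table", {
  out <- generate_session(small_cfg(global_rate = 0, local_rate = 0))
  expect_equal(nrow(out$truth$burst_events), 0)
})

test_that("event counts fall in the Poisson 99% interval", {
  # counts of each class against the qpois oracle for rate * duration
  cfg <- synth_config(session_duration = 100, n_cortical_channels = 16,
                      n_subcortical_channels = 4, n_units = 2, seed = 3)
  out <- generate_session(cfg)
  ev <- out$truth$burst_events
  for (cls in c("global", "local")) {
    lambda <- if (cls == "global") cfg$global_rate else cfg$local_rate
    lambda <- lambda * cfg$session_duration
    n <- sum(ev$class == cls)
    expect_gte(n, stats::qpois(0.005, lambda))
    expect_lte(n, stats::qpois(0.995, lambda))
  }
})

test_that("overlong event demand errors out", {
  expect_error(
    generate_session(small_cfg(session_duration = 3, global_rate = 5)),
    "too short")
})

test_that("inject_bursts: identity on empty list, error outside span", {
  bg <- matrix(stats::rnorm(1000 * 4), ncol = 4)
  empty <- data.frame()
  expect_identical(inject_bursts(bg, empty, 1000), bg)
  bad <- data.frame(class = "global", start_s = 0.9, end_s = 1.2,
                    freq_hz = 20, amplitude = 1, phase0 = 0,
                    subcortical = FALSE, channels = I(list(1:2)))
  expect_error(inject_bursts(bg, bad, 1000), "outside")
})

test_that("a single global event leaves an envelope bump on every channel", {
  fs <- 1000
  bg <- matrix(0, 4000, 6)
  ev <- data.frame(class = "global", start_s = 1.5, end_s = 2.0,
                   freq_hz = 20, amplitude = 1.5, phase0 = 0.3,
                   subcortical = FALSE, channels = I(list(1:6)))
  x <- inject_bursts(bg, ev, fs)
  for (ch in 1:6) {
    env <- Mod(analytic_signal(x[, ch]))
    inside <- env[1600:1900]
    expect_gt(max(inside), 1.2)          # near the 1.5 Hann peak
    expect_lt(max(env[1:1400]), 0.1)     # quiet outside the event
  }
})

test_that("local event channels all lie within the cluster radius", {
  cfg <- small_cfg(local_rate = 0.5, global_rate = 0,
                   local_params = burst_class_params(
                     amplitude = 1.2, duration_mean = 0.2, freq_mean = 27,
                     footprint = 0.6, p_subcortical = 0.1))
  out <- generate_session(cfg)
  geom <- out$bundle$geometry
  ev <- out$truth$burst_events
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    ch <- ev$channels[[i]]
    # all involved channels within 0.6 mm of *some* center: check pairwise
    # spread instead (diameter <= 1.2 mm)
    dx <- outer(geom$x_mm[ch], geom$x_mm[ch], "-")
    dy <- outer(geom$y_mm[ch], geom$y_mm[ch], "-")
    expect_lte(max(sqrt(dx^2 + dy^2)), 1.2 + 1e-9)
    expect_gte(length(ch), 3)
  }
})

test_that("kappa = 0 spikes are phase-uniform; negative kappa errors", {
  cfg <- synth_config(session_duration = 120, n_units = 1, base_rate = 60,
                      kappa_global = 0, kappa_local = 0, seed = 5,
                      global_rate_scale = 1)
  ev <- data.frame(class = "global", start_s = seq(1, 115, by = 2),
                   freq_hz = 21, amplitude = 2, phase0 = 0,
                   subcortical = FALSE)
  ev$end_s <- ev$start_s + 1.5
  ev$channels <- I(rep(list(1:4), nrow(ev)))
  set.seed(5)
  sp <- generate_entrained_spikes(ev, cfg)
  ph <- event_phase_at(ev, sp$spikes[[1]])
  ph <- ph[!is.na(ph)]
  expect_gt(length(ph), 3000)
  oct <- cut(ph, breaks = seq(-pi, pi, length.out = 9))
  expect_gt(stats::chisq.test(table(oct))$p.value, 0.01)
  expect_error(generate_entrained_spikes(ev, synth_config(kappa_global = -1)),
               "non-negative")
})

test_that("large kappa concentrates in-burst spikes near the preferred phase", {
  cfg <- synth_config(session_duration = 60, n_units = 1, base_rate = 40,
                      kappa_global = 50, kappa_local = 50, seed = 6)
  ev <- data.frame(class = "global", start_s = seq(1, 55, by = 2),
                   freq_hz = 21, amplitude = 2, phase0 = 0,
                   subcortical = FALSE)
  ev$end_s <- ev$start_s + 1.5
  ev$channels <- I(rep(list(1:4), nrow(ev)))
  set.seed(6)
  sp <- generate_entrained_spikes(
    ev, cfg, coupling = data.frame(unit = 1, pref_phase = 0.7,
                                   kappa_global = 50, kappa_local = 50))
  ph <- event_phase_at(ev, sp$spikes[[1]])
  ph <- ph[!is.na(ph)]
  dev <- abs(Arg(exp(1i * (ph - 0.7))))
  expect_gt(mean(dev < pi / 8), 0.95)
})

test_that("global_rate_scale halves the in-burst firing rate", {
  cfg <- synth_config(session_duration = 200, n_units = 1, base_rate = 30,
                      kappa_global = 0, kappa_local = 0,
                      global_rate_scale = 0.5, seed = 7)
  ev <- data.frame(class = "global", start_s = seq(1, 195, by = 2),
                   freq_hz = 21, amplitude = 2, phase0 = 0,
                   subcortical = FALSE)
  ev$end_s <- ev$start_s + 1
  ev$channels <- I(rep(list(1:4), nrow(ev)))
  set.seed(7)
  sp <- generate_entrained_spikes(ev, cfg)
  st <- sp$spikes[[1]]
  inb <- vapply(st, function(t) any(t >= ev$start_s & t < ev$end_s), TRUE)
  t_in <- sum(ev$end_s - ev$start_s)
  t_out <- cfg$session_duration - t_in
  r_in <- sum(inb) / t_in
  r_out <- sum(!inb) / t_out
  # within Poisson error of the configured 0.5 ratio
  expect_equal(r_in / r_out, 0.5, tolerance = 0.1)
})

test_that("kinematics: bell speed, slowdown contrast and the 0.1-peak rule", {
  cfg <- small_cfg(global_rate = 0)
  out <- generate_session(cfg)
  b <- out$bundle
  sp <- hand_speed(b$kinematics$x_mm, NULL, b$frame_rate)
  tr <- b$trials[1, ]
  sel <- b$kinematics$time_s >= tr$door_open &
    b$kinematics$time_s <= tr$grasp_start
  v <- sp[sel]
  expect_equal(sum(diff(sign(diff(v[!is.na(v)]))) < 0), 1)  # single peak
  # speed below 0.1 x peak before the true onset
  pre <- sp[b$kinematics$time_s < tr$reach_start - 0.02 &
              b$kinematics$time_s > tr$door_open]
  expect_true(all(pre < 0.1 * max(v, na.rm = TRUE), na.rm = TRUE))

  # slowdown interval reduces in-interval speed
  slow <- data.frame(start_s = tr$peak_time - 0.05, end_s = tr$peak_time + 0.05)
  kin2 <- generate_trial_kinematics(b$trials, slow, cfg)
  sp2 <- hand_speed(kin2$frames$x_mm, NULL, cfg$frame_rate)
  inside <- kin2$frames$time_s >= slow$start_s & kin2$frames$time_s < slow$end_s
  expect_lt(mean(sp2[inside], na.rm = TRUE), mean(sp[inside], na.rm = TRUE))
})

test_that("injected events carry more band power than matched quiet windows", {
  out <- generate_session(small_cfg())
  b <- out$bundle
  ab <- beta_series_fft(b$lfp_cortex, b$fs_raw, 3, b$beta_band, 3)
  ev <- out$truth$burst_events
  hits <- 0; total <- 0
  for (i in seq_len(nrow(ev))) {
    ch <- ev$channels[[i]][1]
    i0 <- floor(ev$start_s[i] * ab$fs) + 1
    i1 <- floor(ev$end_s[i] * ab$fs)
    len <- i1 - i0 + 1
    ref0 <- i0 - 2 * len
    if (ref0 < 1) next
    # reference window must be clear of all injected events
    r_start <- (ref0 - 1) / ab$fs; r_end <- r_start + len / ab$fs
    if (any(ev$start_s < r_end + 0.05 & ev$end_s > r_start - 0.05 &
              seq_len(nrow(ev)) != i)) next
    total <- total + 1
    if (mean(ab$amplitude[i0:i1, ch]^2) >
          mean(ab$amplitude[ref0:(ref0 + len - 1), ch]^2))
      hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})
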