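# Behavior layer: event detection from kinematics, normalization, recovery
# index, epochs, and the burst-behavior summaries.

test_that("reach/grasp onsets are recovered within one frame", {
  cfg <- synth_config(session_duration = 120, n_cortical_channels = 16,
                      n_subcortical_channels = 4, n_units = 2,
                      global_rate = 0, seed = 5)
  out <- generate_session(cfg)
  b <- out$bundle
  det <- detect_session_events(b$kinematics, b$trials, b$crossing_offset,
                               b$frame_rate)
  expect_false(any(det$flagged))
  # ground truth quantized to the frame clock (the detector marks frames)
  frame <- function(t) floor(t * b$frame_rate) / b$frame_rate
  expect_true(all(abs(det$reach_start - frame(b$trials$reach_start)) <=
                    1 / b$frame_rate + 1e-9))
  expect_true(all(abs(det$grasp_start - frame(b$trials$grasp_start)) <=
                    1 / b$frame_rate + 1e-9))
})

test_that("event detection shifts with the frame clock (equivariance)", {
  fr <- 50
  tt <- seq(0, 6, by = 1 / fr)
  v <- 300 * exp(-0.5 * ((tt - 3) / 0.2)^2)
  x <- cumsum(v) / fr
  f1 <- data.frame(time_s = tt, x_mm = x, y_mm = 0)
  e1 <- detect_reach_grasp_events(f1, max(x) / 2, fr)
  f2 <- f1; f2$time_s <- f1$time_s + 10
  e2 <- detect_reach_grasp_events(f2, max(x) / 2, fr)
  expect_equal(e2$reach_start - e1$reach_start, 10)
  expect_equal(e2$grasp_start - e1$grasp_start, 10)
})

test_that("no crossing or monotone speed flags the trial", {
  fr <- 50
  tt <- seq(0, 6, by = 1 / fr)
  # never crosses the line
  f <- data.frame(time_s = tt, x_mm = rep(0, length(tt)), y_mm = 0)
  ev <- detect_reach_grasp_events(f, 10, fr)
  expect_true(ev$flagged)
  expect_true(is.na(ev$reach_start))
  # speed never drops below 0.1 x peak after the peak
  f2 <- data.frame(time_s = tt, x_mm = 100 * tt, y_mm = 0)  # constant speed
  ev2 <- detect_reach_grasp_events(f2, 300, fr)
  expect_true(is.na(ev2$grasp_start))
})

test_that("normalized duration is a per-slot ratio", {
  tab <- data.frame(slot = c("a", "b", "c"),
                    mean_trial_s = c(2, 4, 0.5))
  expect_equal(normalized_duration(2, "a", tab), 1)
  expect_equal(normalized_duration(4, "a", tab), 2)
  expect_equal(normalized_duration(c(4, 1), c("b", "c"), tab), c(1, 2))
  expect_error(normalized_duration(1, "zzz", tab), "slot")
})

test_that("recovery index endpoints and the toy two-day series", {
  pres <- data.frame(slot = "s", mean_trial_s = 1)
  mk <- function(day, tt) data.frame(day = day, slot = "s", rewarded = TRUE,
                                     reach_start = 0, reward_time = tt)
  # day-averaged normalized times {3.0, 2.0} -> indices {0, 0.5}
  tr <- rbind(mk(1, 3), mk(2, 2))
  ri <- recovery_index(tr, pres)
  expect_equal(ri$recovery_index, c(0, 0.5))
  # a day at pre-stroke parity scores exactly 1
  tr2 <- rbind(mk(1, 3), mk(2, 1))
  expect_equal(recovery_index(tr2, pres)$recovery_index, c(0, 1))
  # unrewarded trials count as the 10 s timeout
  tr3 <- rbind(mk(1, 3), data.frame(day = 1, slot = "s", rewarded = FALSE,
                                    reach_start = 0, reward_time = NA))
  ri3 <- recovery_index(tr3, pres)
  expect_equal(ri3$mean_norm_time, 6.5)   # mean of 3 and 10
  expect_equal(ri3$percent_correct, 0.5)
  # first day without deficit is an error
  expect_error(recovery_index(mk(1, 1), pres), "deficit")
})

test_that("epoch definitions follow the reward / timeout rule", {
  tr <- data.frame(trial = 1:3, door_open = c(0, 20, 40),
                   reach_start = c(1, 21, 41), grasp_start = c(2, 22, NA),
                   rewarded = c(TRUE, FALSE, TRUE),
                   reward_time = c(5, NA, 45))
  ep <- define_epochs(tr)
  expect_equal(ep$reach$start, c(1, 21))
  expect_equal(ep$reach$end, c(2, 22))
  expect_equal(ep$grasp$end[1], 5)          # rewarded: ends at reward
  expect_equal(ep$grasp$end[2], 30)         # unrewarded: door open + 10
  expect_false(3 %in% ep$grasp$trial)       # undefined grasp start dropped
})

test_that("aligned burst fraction counts trials once and respects the window", {
  events <- data.frame(category = "global",
                       start_s = c(1.0, 1.1, 10.2, 20.0),
                       end_s = c(1.2, 1.3, 10.5, 20.4))
  aligns <- c(1.0, 10.0, 20.9, 30.0)   # trials 1-3 of 4; trial 3 misses
  expect_equal(align_burst_fraction(events, aligns, 0.35, "global"), 0.5)
  # burst overlapping on 3 of 4 trials
  aligns2 <- c(1.0, 10.0, 20.2, 30.0)
  expect_equal(align_burst_fraction(events, aligns2, 0.35, "global"), 0.75)
  # window width 0: only bursts spanning the exact instant
  expect_equal(align_burst_fraction(events, c(1.1), 0, "global"), 1)
  expect_equal(align_burst_fraction(events, c(5), 0, "global"), 0)
  expect_true(is.na(align_burst_fraction(events, NA_real_, 0.35, "global")))
})

test_that("burst occupancy is the covered fraction of reach-to-last-lift", {
  pres <- data.frame(slot = "s", mean_trial_s = 2)
  trials <- data.frame(trial = 1:2, reach_start = c(0, 10),
                       last_lift = c(4, 14), slot = "s")
  events <- data.frame(category = "global", start_s = 1, end_s = 3)
  occ <- burst_occupancy_vs_trial_time(events, trials, pres, "global")
  expect_equal(occ$occupancy, c(0.5, 0))
  expect_equal(occ$norm_length, c(2, 2))
  # no bursts
  occ0 <- burst_occupancy_vs_trial_time(events[0, ], trials, pres, "global")
  expect_equal(occ0$occupancy, c(0, 0))
})

test_that("speed by burst category masks epochs and averages per category", {
  fs <- 100
  labels <- integer(1000)
  labels[201:400] <- 1L; labels[401:600] <- 2L
  ft <- seq(0, 9.99, by = 0.02)
  speed <- rep(5, length(ft))
  ep <- data.frame(start = 1, end = 7)
  out <- speed_by_burst_category(speed, ft, labels, fs, ep)
  expect_true(all(out$frames$time_s >= 1 & out$frames$time_s < 7))
  expect_equal(as.numeric(out$means), c(5, 5, 5))  # constant speed: equal means
  # speed tied to category
  speed2 <- rep(5, length(ft)); speed2[ft >= 4 & ft < 6] <- 1
  out2 <- speed_by_burst_category(speed2, ft, labels, fs, ep)
  expect_lt(out2$means["global"], out2$means["local"])
})
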