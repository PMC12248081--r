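# Behavioral layer: reach/grasp onset extraction from hand kinematics,
# normalized durations, percent correct, recovery index, epoch intervals,
# and the burst-behavior summaries (trial-fraction alignment, burst
# occupancy vs trial length, speed by burst category).

# Gaussian temporal smoothing that ignores missing samples (NaN-aware):
# kernel length 11 frames (210 ms at 50 Hz), SD 1 frame.
gaussian_smooth_na <- function(x, len = 11, sd = 1) {
  half <- (len - 1) / 2
  k <- exp(-0.5 * ((-half):half / sd)^2)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half):min(n, i + half)
    w <- k[idx - i + half + 1]
    ok <- !is.na(x[idx])
    if (any(ok)) out[i] <- sum(w[ok] * x[idx][ok]) / sum(w[ok])
  }
  out
}

#' Hand speed from a position trace
#'
#' First differences of the Gaussian-smoothed positions over the frame
#' interval. Missing positions propagate to missing speeds.
#'
#' @param x,y Position coordinates per frame (y may be NULL).
#' @param frame_rate Hz.
#' @return Speed per frame (first element NA).
#' @export
hand_speed <- function(x, y = NULL, frame_rate) {
  cdiff <- function(v) {        # central differences, NA at the ends
    n <- length(v)
    c(NA, (v[3:n] - v[1:(n - 2)]) / 2, NA)
  }
  dx <- cdiff(gaussian_smooth_na(x))
  if (!is.null(y)) {
    dy <- cdiff(gaussian_smooth_na(y))
    sqrt(dx^2 + dy^2) * frame_rate
  } else abs(dx) * frame_rate
}

#' Detect reach start and grasp start for one trial
#'
#' The crossing frame is the first in-window frame at which the position
#' crosses the apparatus line; peak hand speed is searched in a +/-200 ms
#' window around it; reach start is the last frame before the peak with
#' speed below `0.1 * peak`, grasp start the first frame after it below
#' the same bound. Trials without a crossing frame are flagged and carry
#' no events.
#'
#' @param frames `data.frame(time_s, x_mm[, y_mm])`, restricted to one
#'   trial's analysis window (door open to trial end).
#' @param crossing_x Apparatus line position, mm (same axis as `x_mm`).
#' @param frame_rate Hz.
#' @param peak_window Half-width of the peak search window, s.
#' @param frac Onset/offset speed fraction of the peak (default 0.1).
#' @return `list(reach_start, grasp_start, crossing_time, peak_speed,
#'   flagged)`; times are `NA` when undefined.
#' @export
detect_reach_grasp_events <- function(frames, crossing_x, frame_rate,
                                      peak_window = 0.2, frac = 0.1) {
  und <- list(reach_start = NA_real_, grasp_start = NA_real_,
              crossing_time = NA_real_, peak_speed = NA_real_, flagged = TRUE)
  sp <- hand_speed(frames$x_mm, frames$y_mm, frame_rate)
  cross <- which(!is.na(frames$x_mm) & frames$x_mm >= crossing_x)
  if (!length(cross)) return(und)
  ci <- cross[1]
  win <- which(abs(frames$time_s - frames$time_s[ci]) <= peak_window &
                 !is.na(sp))
  if (!length(win)) return(und)
  pi_ <- win[which.max(sp[win])]
  peak <- sp[pi_]
  thr <- frac * peak
  before <- which(seq_along(sp) < pi_ & !is.na(sp) & sp < thr)
  after <- which(seq_along(sp) > pi_ & !is.na(sp) & sp < thr)
  list(reach_start = if (length(before)) frames$time_s[max(before)] else NA_real_,
       grasp_start = if (length(after)) frames$time_s[min(after)] else NA_real_,
       crossing_time = frames$time_s[ci], peak_speed = peak, flagged = FALSE)
}

#' Detect reach/grasp events for every trial of a session
#'
#' @param kinematics Session `data.frame(time_s, x_mm[, y_mm])`.
#' @param trials Trial table with `door_open` (and optionally `last_lift`).
#' @param crossing_offset Crossing-line offset from the door-open position,
#'   mm.
#' @param frame_rate Hz.
#' @param window_s Analysis window length after door open, s.
#' @return `data.frame(trial, reach_start, grasp_start, flagged)`.
#' @export
detect_session_events <- function(kinematics, trials, crossing_offset,
                                  frame_rate, window_s = 10) {
  res <- lapply(seq_len(nrow(trials)), function(i) {
    sel <- kinematics$time_s >= trials$door_open[i] &
      kinematics$time_s <= trials$door_open[i] + window_s
    fr <- kinematics[sel, , drop = FALSE]
    if (nrow(fr) < 12)
      return(data.frame(trial = trials$trial[i], reach_start = NA_real_,
                        grasp_start = NA_real_, flagged = TRUE))
    line <- fr$x_mm[1] + crossing_offset
    ev <- detect_reach_grasp_events(fr, line, frame_rate)
    data.frame(trial = trials$trial[i], reach_start = ev$reach_start,
               grasp_start = ev$grasp_start, flagged = ev$flagged)
  })
  do.call(rbind, res)
}

#' Normalized trial duration
#'
#' @param duration Trial duration, s.
#' @param slot Slot type of the trial.
#' @param prestroke `data.frame` with columns `slot` and the pre-stroke
#'   mean duration named in `column`.
#' @param column Name of the pre-stroke mean column.
#' @return Dimensionless ratio (1 = on par with pre-stroke).
#' @export
normalized_duration <- function(duration, slot, prestroke,
                                column = "mean_trial_s") {
  i <- match(slot, prestroke$slot)
  if (any(is.na(i))) stop("slot not present in the pre-stroke table")
  m <- prestroke[[column]][i]
  if (any(m <= 0)) stop("pre-stroke mean must be positive")
  duration / m
}

#' Per-day recovery index
#'
#' Trial time is reach start to reward for rewarded trials and the timeout
#' (10 s) for unrewarded ones; each trial time is normalized by the
#' pre-stroke per-slot mean, averaged per day, decremented by 1, divided by
#' the first day's value and subtracted from 1 — so 0 means a deficit as
#' large as the first post-stroke day and 1 means pre-stroke parity.
#'
#' @param trials `data.frame(day, slot, rewarded, reach_start, reward_time)`.
#' @param prestroke Per-slot pre-stroke table (column `mean_trial_s`).
#' @param timeout Unrewarded trial time, s (default 10).
#' @param early_late_threshold Recovery-index threshold for the early/late
#'   session tag (default 0.5).
#' @return `data.frame(day, mean_norm_time, percent_correct,
#'   recovery_index, phase)`.
#' @export
recovery_index <- function(trials, prestroke, timeout = 10,
                           early_late_threshold = 0.5) {
  tt <- ifelse(trials$rewarded, trials$reward_time - trials$reach_start,
               timeout)
  norm <- normalized_duration(tt, trials$slot, prestroke)
  days <- sort(unique(trials$day))
  mean_norm <- vapply(days, function(d) mean(norm[trials$day == d]), 0)
  pc <- vapply(days, function(d) mean(trials$rewarded[trials$day == d]), 0)
  first <- mean_norm[1] - 1
  if (first <= 0)
    stop("first post-stroke day shows no deficit; recovery index undefined")
  ri <- 1 - (mean_norm - 1) / first
  data.frame(day = days, mean_norm_time = mean_norm, percent_correct = pc,
             recovery_index = ri,
             phase = ifelse(ri < early_late_threshold, "early", "late"))
}

#' Reach and grasp epoch intervals per trial
#'
#' Reach: `[reach_start, grasp_start)`. Grasp: `[grasp_start, reward)` for
#' rewarded trials, else `[grasp_start, door_open + timeout)`.
#'
#' @param trials Trial table (`reach_start`, `grasp_start`, `rewarded`,
#'   `reward_time`, `door_open`).
#' @param timeout Trial timeout, s.
#' @return List of two data.frames `reach` and `grasp`
#'   (`trial`, `start`, `end`); trials with undefined bounds are omitted.
#' @export
define_epochs <- function(trials, timeout = 10) {
  reach <- data.frame(trial = trials$trial, start = trials$reach_start,
                      end = trials$grasp_start)
  gend <- ifelse(!is.na(trials$rewarded) & trials$rewarded &
                   !is.na(trials$reward_time),
                 trials$reward_time, trials$door_open + timeout)
  grasp <- data.frame(trial = trials$trial, start = trials$grasp_start,
                      end = gend)
  ok <- function(d) d[!is.na(d$start) & !is.na(d$end) & d$end > d$start, ,
                      drop = FALSE]
  list(reach = ok(reach), grasp = ok(grasp))
}

#' Fraction of trials with a burst near a behavioral event
#'
#' A trial counts (once, regardless of event count) if any burst of the
#' category overlaps `[t - window, t + window]` around the trial's
#' alignment time.
#'
#' @param events Burst event table (`category`, `start_s`, `end_s`).
#' @param align_times Per-trial alignment times, s (NA trials dropped).
#' @param window Half-width, s (default 0.35).
#' @param category Burst category to count.
#' @return Fraction in `[0, 1]`, or `NA` if no trial has the event.
#' @export
align_burst_fraction <- function(events, align_times, window = 0.35,
                                 category = "global") {
  align_times <- align_times[!is.na(align_times)]
  if (!length(align_times)) return(NA_real_)
  ev <- events[events$category == category, , drop = FALSE]
  hit <- vapply(align_times, function(t)
    any(ev$start_s <= t + window & ev$end_s >= t - window), TRUE)
  mean(hit)
}

#' Burst occupancy versus trial length
#'
#' Occupancy is the fraction of `[reach_start, last_lift)` covered by
#' events of the category; paired with the trial's normalized length over
#' the same interval.
#'
#' @param events Burst event table.
#' @param trials Trial table (`reach_start`, `last_lift`, `slot`).
#' @param prestroke Per-slot pre-stroke table for length normalization.
#' @param category Burst category.
#' @return `data.frame(trial, occupancy, norm_length)`; zero-length or
#'   undefined intervals are skipped.
#' @export
burst_occupancy_vs_trial_time <- function(events, trials, prestroke,
                                          category = "global") {
  ev <- events[events$category == category, , drop = FALSE]
  res <- lapply(seq_len(nrow(trials)), function(i) {
    s <- trials$reach_start[i]; e <- trials$last_lift[i]
    if (is.na(s) || is.na(e) || e <= s) return(NULL)
    ov <- sum(pmax(0, pmin(ev$end_s, e) - pmax(ev$start_s, s)))
    data.frame(trial = trials$trial[i], occupancy = ov / (e - s),
               norm_length = normalized_duration(e - s, trials$slot[i],
                                                 prestroke))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(trial = integer(0), occupancy = numeric(0),
                               norm_length = numeric(0)) else out
}

#' Hand speed by burst category
#'
#' Maps each camera frame inside the supplied epochs to the nearest LFP
#' label sample and reports per-category frame speeds and means. Frames
#' outside any epoch are excluded.
#'
#' @param speed Per-frame hand speed.
#' @param frame_times Frame times, s.
#' @param labels Per-sample 0/1/2 labels.
#' @param fs LFP sampling rate, Hz.
#' @param epochs `data.frame(start, end)` epoch intervals.
#' @return List: `frames` data.frame(time_s, speed, category), `means`
#'   named vector over categories.
#' @export
speed_by_burst_category <- function(speed, frame_times, labels, fs, epochs) {
  in_ep <- rep(FALSE, length(frame_times))
  for (i in seq_len(nrow(epochs)))
    in_ep <- in_ep | (frame_times >= epochs$start[i] &
                        frame_times < epochs$end[i])
  keep <- in_ep & !is.na(speed)
  idx <- pmin(pmax(round(frame_times[keep] * fs) + 1L, 1L), length(labels))
  cat <- c("none", "local", "global")[labels[idx] + 1L]
  fr <- data.frame(time_s = frame_times[keep], speed = speed[keep],
                   category = cat)
  means <- tapply(fr$speed, factor(fr$category,
                                   levels = c("none", "local", "global")),
                  mean)
  list(frames = fr, means = means)
}
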