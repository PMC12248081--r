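# Synthetic session generator: pink-noise multichannel LFP with injected
# narrow-band bursts of two classes (array-wide "global" vs spatially
# clustered "local"), phase-coupled Poisson spike trains, and reach-to-grasp
# kinematics with slowdowns tied to global bursts. Every generated structure
# is returned alongside its ground truth so downstream detection,
# classification, entrainment and behavior stages can be scored exactly.

#' Parameters of one burst class
#'
#' @param amplitude Peak envelope amplitude of the injected burst, in units of
#'   the (unit-variance) background signal.
#' @param duration_mean Mean burst duration in seconds (must be >= 0.1 s, the
#'   detector's minimum duration).
#' @param duration_sd SD of the burst duration (s); durations are truncated
#'   below at 0.12 s.
#' @param freq_mean Mean burst oscillation frequency in Hz; must lie inside
#'   the configured beta band.
#' @param freq_sd Per-event frequency jitter (Hz).
#' @param footprint `"all"` for array-wide events (plus subcortical
#'   coincidence), or a cluster radius in mm for spatially local events.
#' @param p_subcortical Probability that an event is accompanied by a
#'   coincident subcortical burst.
#' @export
burst_class_params <- function(amplitude, duration_mean, freq_mean,
                               footprint = "all", duration_sd = 0.05,
                               freq_sd = 1, p_subcortical = 0.5) {
  stopifnot(amplitude > 0, duration_mean >= 0.1, freq_mean > 0,
            p_subcortical >= 0, p_subcortical <= 1)
  structure(list(amplitude = amplitude, duration_mean = duration_mean,
                 duration_sd = duration_sd, freq_mean = freq_mean,
                 freq_sd = freq_sd, footprint = footprint,
                 p_subcortical = p_subcortical),
            class = "burst_class_params")
}

#' Synthetic session configuration
#'
#' Defaults state the world the downstream analyses assume: an 8x8 cortical
#' array at 0.5 mm column / 0.375 mm row pitch sampled at 3051.8 Hz, a
#' subcortical probe, beta band 15-35 Hz, global bursts that are
#' higher-amplitude / longer / lower-frequency and nearly always
#' subcortically coincident, local bursts that are clustered on the array,
#' spike trains phase-coupled more strongly to global bursts with firing-rate
#' suppression during them, and reach kinematics that slow down inside global
#' bursts.
#'
#' @param n_cortical_channels Number of cortical channels (laid out on a
#'   near-square grid, default 64 = 8x8).
#' @param n_subcortical_channels Number of subcortical channels.
#' @param fs_raw Raw sampling rate, Hz.
#' @param x_spacing,y_spacing Electrode column/row pitch, mm.
#' @param session_duration Session length, s.
#' @param beta_band `c(low, high)` Hz.
#' @param global_rate,local_rate Event rates, events/s.
#' @param global_params,local_params [burst_class_params()] for each class.
#' @param n_units Number of spiking units.
#' @param kappa_global,kappa_local von Mises concentration of spike-phase
#'   coupling during each burst class.
#' @param base_rate Baseline unit firing rate, Hz.
#' @param global_rate_scale Multiplicative firing-rate factor inside global
#'   bursts (< 1 means suppression).
#' @param noise_exponent 1/f^alpha slope of the background spectrum.
#' @param common_mode Fraction of background variance shared across channels.
#' @param slowdown_factor Hand-speed multiplier inside global-burst
#'   slowdown intervals.
#' @param trial_gap Mean spacing between trial starts, s.
#' @param frame_rate Camera frame rate, Hz.
#' @param seed Integer RNG seed; identical configs give bit-identical output.
#' @export
synth_config <- function(n_cortical_channels = 64, n_subcortical_channels = 32,
                         fs_raw = 3051.8, x_spacing = 0.5, y_spacing = 0.375,
                         session_duration = 300, beta_band = c(15, 35),
                         global_rate = 0.25, local_rate = 0.40,
                         global_params = NULL, local_params = NULL,
                         n_units = 12, kappa_global = 1.5, kappa_local = 0.5,
                         base_rate = 10, global_rate_scale = 0.5,
                         noise_exponent = 1.5, common_mode = 0.2,
                         slowdown_factor = 0.35, trial_gap = 12,
                         frame_rate = 50, seed = 1L) {
  stopifnot(x_spacing > 0, y_spacing > 0, global_rate >= 0, local_rate >= 0,
            beta_band[1] > 0, beta_band[1] < beta_band[2],
            beta_band[2] < fs_raw / 2, session_duration > 0)
  if (is.null(global_params))
    global_params <- burst_class_params(amplitude = 2.0, duration_mean = 0.35,
                                        freq_mean = 21, footprint = "all",
                                        p_subcortical = 0.9)
  if (is.null(local_params))
    local_params <- burst_class_params(amplitude = 1.2, duration_mean = 0.20,
                                       duration_sd = 0.04, freq_mean = 27,
                                       footprint = 0.8, p_subcortical = 0.1)
  for (p in list(global_params, local_params))
    stopifnot(p$freq_mean >= beta_band[1], p$freq_mean <= beta_band[2])
  structure(list(
    n_cortical_channels = n_cortical_channels,
    n_subcortical_channels = n_subcortical_channels, fs_raw = fs_raw,
    x_spacing = x_spacing, y_spacing = y_spacing,
    session_duration = session_duration, beta_band = beta_band,
    global_rate = global_rate, local_rate = local_rate,
    global_params = global_params, local_params = local_params,
    n_units = n_units, kappa_global = kappa_global,
    kappa_local = kappa_local, base_rate = base_rate,
    global_rate_scale = global_rate_scale, noise_exponent = noise_exponent,
    common_mode = common_mode, slowdown_factor = slowdown_factor,
    trial_gap = trial_gap, frame_rate = frame_rate, seed = as.integer(seed)),
    class = "synth_config")
}

#' Electrode grid geometry
#'
#' Row-major channel indexing on an `nrow x ncol` grid; origin at channel 1.
#'
#' @param n_channels Channel count.
#' @param x_spacing,y_spacing Column/row pitch, mm.
#' @return `data.frame(channel, x_mm, y_mm)`.
#' @export
grid_geometry <- function(n_channels, x_spacing = 0.5, y_spacing = 0.375) {
  ncol <- ceiling(sqrt(n_channels))
  idx <- seq_len(n_channels) - 1L
  data.frame(channel = seq_len(n_channels),
             x_mm = (idx %% ncol) * x_spacing,
             y_mm = (idx %/% ncol) * y_spacing)
}

# 1/f^alpha background noise, unit variance per channel, with a shared
# common-mode component so channels are weakly correlated like real arrays.
pink_noise_matrix <- function(n, n_channels, fs, alpha, common_mode) {
  m <- stats::nextn(n, c(2, 3, 5))
  freqs <- c(1, seq_len(m - 1)) * fs / m
  freqs <- pmin(freqs, fs - freqs)           # two-sided spectrum, guard DC
  shape <- freqs^(-alpha / 2)
  shape[1] <- 0
  # one complex-white FFT yields two independent pink channels (Re and Im)
  pair <- function() {
    spec <- shape * (stats::rnorm(m) + 1i * stats::rnorm(m))
    x <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
    list(Re(x) / stats::sd(Re(x)), Im(x) / stats::sd(Im(x)))
  }
  a <- sqrt(common_mode); b <- sqrt(1 - common_mode)
  shared <- a * pair()[[1]]
  out <- matrix(0, n, n_channels)
  j <- 1
  while (j <= n_channels) {
    p <- pair()
    out[, j] <- shared + b * p[[1]]
    if (j + 1 <= n_channels) out[, j + 1] <- shared + b * p[[2]]
    j <- j + 2
  }
  out
}

# Schedule non-overlapping burst events of both classes. Returns a data.frame
# with one row per event; channel membership is a list-column.
schedule_burst_events <- function(config) {
  dur <- config$session_duration
  margin <- 0.5                 # keep clear of session edges
  classes <- c("global", "local")
  rates <- c(config$global_rate, config$local_rate)
  rows <- list()
  occupied <- matrix(numeric(0), ncol = 2)  # (start, end) of placed events
  geom <- grid_geometry(config$n_cortical_channels,
                        config$x_spacing, config$y_spacing)
  for (k in 1:2) {
    cls <- classes[k]
    p <- if (cls == "global") config$global_params else config$local_params
    n_ev <- stats::rpois(1, rates[k] * dur)
    if (n_ev == 0) next
    expect_occ <- sum(rates * dur *
      c(config$global_params$duration_mean, config$local_params$duration_mean))
    if (expect_occ > 0.7 * dur || dur < 2 * margin + p$duration_mean)
      stop("session too short to place requested burst events")
    placed <- 0; attempts <- 0
    while (placed < n_ev) {
      attempts <- attempts + 1
      if (attempts > 50 * n_ev)
        stop("session too short to place requested burst events")
      d <- max(0.15, stats::rnorm(1, p$duration_mean, p$duration_sd))
      s <- stats::runif(1, margin, dur - margin - d)
      e <- s + d
      gap <- 0.15               # separation so detected events stay distinct
      if (nrow(occupied) &&
          any(s - gap < occupied[, 2] & e + gap > occupied[, 1])) next
      occupied <- rbind(occupied, c(s, e))
      f <- stats::rnorm(1, p$freq_mean, p$freq_sd)
      f <- min(max(f, config$beta_band[1]), config$beta_band[2])
      if (identical(p$footprint, "all")) {
        chans <- geom$channel
      } else {
        radius <- as.numeric(p$footprint)
        repeat {
          cx <- stats::runif(1, min(geom$x_mm), max(geom$x_mm))
          cy <- stats::runif(1, min(geom$y_mm), max(geom$y_mm))
          dist <- sqrt((geom$x_mm - cx)^2 + (geom$y_mm - cy)^2)
          chans <- geom$channel[dist <= radius]
          if (length(chans) >= 3) break
        }
      }
      sub <- stats::runif(1) < p$p_subcortical
      rows[[length(rows) + 1]] <- list(
        class = cls, start_s = s, end_s = e, freq_hz = f,
        amplitude = p$amplitude, phase0 = stats::runif(1, 0, 2 * pi),
        subcortical = sub, channels = list(chans))
      placed <- placed + 1
    }
  }
  if (!length(rows))
    return(data.frame(class = character(0), start_s = numeric(0),
                      end_s = numeric(0), freq_hz = numeric(0),
                      amplitude = numeric(0), phase0 = numeric(0),
                      subcortical = logical(0),
                      channels = I(list())))
  ev <- do.call(rbind, lapply(rows, function(r)
    data.frame(class = r$class, start_s = r$start_s, end_s = r$end_s,
               freq_hz = r$freq_hz, amplitude = r$amplitude,
               phase0 = r$phase0, subcortical = r$subcortical,
               channels = I(r$channels))))
  rownames(ev) <- NULL
  ev[order(ev$start_s), , drop = FALSE]
}

#' Inject amplitude-enveloped burst oscillations into a background signal
#'
#' Each event adds a Hann-windowed sinusoid at its event frequency to its
#' involved channels. The background is not otherwise modified; an empty
#' event list returns the background unchanged.
#'
#' @param background Samples-by-channels numeric matrix.
#' @param events Event table as produced by the scheduler: columns `start_s`,
#'   `end_s`, `freq_hz`, `amplitude`, `phase0` and list-column `channels`.
#' @param fs Sampling rate of `background`, Hz.
#' @return Matrix of the same shape with bursts added.
#' @export
inject_bursts <- function(background, events, fs) {
  n <- nrow(background)
  if (is.null(events) || nrow(events) == 0) return(background)
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$start_s[i] * fs) + 1
    i1 <- floor(events$end_s[i] * fs)
    if (i0 < 1 || i1 > n) stop("burst event outside signal span")
    len <- i1 - i0 + 1
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
    tt <- (seq(i0, i1) - 1) / fs
    wave <- events$amplitude[i] * hann *
      sin(2 * pi * events$freq_hz[i] * (tt - events$start_s[i]) +
            events$phase0[i])
    chans <- events$channels[[i]]
    background[i0:i1, chans] <- background[i0:i1, chans, drop = FALSE] + wave
  }
  background
}

# Instantaneous burst phase (analytic-signal convention: phase of cos) at
# arbitrary times inside an event; NA outside.
event_phase_at <- function(events, times) {
  ph <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(events))) {
    inside <- times >= events$start_s[i] & times < events$end_s[i]
    if (!any(inside)) next
    # injected waveform is sin(theta) = cos(theta - pi/2)
    theta <- 2 * pi * events$freq_hz[i] * (times[inside] - events$start_s[i]) +
      events$phase0[i]
    ph[inside] <- wrap_pi(theta - pi / 2)
  }
  ph
}

# wrap angles into (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Generate phase-entrained inhomogeneous Poisson spike trains
#'
#' Inside burst events the firing intensity is modulated by
#' `exp(kappa * cos(phase - preferred)) / I0(kappa)` (unit mean over phase);
#' inside global events the base rate is additionally multiplied by
#' `global_rate_scale`.
#'
#' @param events Scheduled burst events (with phase parameters).
#' @param config A [synth_config()].
#' @param coupling Optional data.frame(unit, pref_phase) to reuse; drawn
#'   uniformly if `NULL`.
#' @return List with `spikes` (named list of spike-time vectors) and
#'   `coupling` (unit, pref_phase, kappa_global, kappa_local).
#' @export
generate_entrained_spikes <- function(events, config, coupling = NULL) {
  if (config$kappa_global < 0 || config$kappa_local < 0)
    stop("kappa must be non-negative")
  dt <- 1e-3
  tt <- seq(0, config$session_duration - dt, by = dt)
  if (is.null(coupling))
    coupling <- data.frame(unit = seq_len(config$n_units),
                           pref_phase = stats::runif(config$n_units, -pi, pi),
                           kappa_global = config$kappa_global,
                           kappa_local = config$kappa_local)
  in_global <- rep(FALSE, length(tt))
  cls_of <- rep(NA_character_, length(tt))
  ph <- event_phase_at(events, tt)
  for (i in seq_len(nrow(events))) {
    idx <- which(tt >= events$start_s[i] & tt < events$end_s[i])
    cls_of[idx] <- events$class[i]
    if (events$class[i] == "global") in_global[idx] <- TRUE
  }
  spikes <- vector("list", config$n_units)
  for (u in seq_len(config$n_units)) {
    lam <- rep(config$base_rate, length(tt))
    lam[in_global] <- lam[in_global] * config$global_rate_scale
    for (cls in c("global", "local")) {
      kap <- if (cls == "global") coupling$kappa_global[u]
             else coupling$kappa_local[u]
      idx <- which(cls_of == cls & !is.na(ph))
      if (length(idx) && kap > 0)
        lam[idx] <- lam[idx] *
          exp(kap * cos(ph[idx] - coupling$pref_phase[u])) /
          besselI(kap, 0)
    }
    p <- pmin(lam * dt, 0.9)
    fire <- stats::runif(length(tt)) < p
    spikes[[u]] <- tt[fire] + dt / 2
  }
  names(spikes) <- paste0("unit", seq_len(config$n_units))
  list(spikes = spikes, coupling = coupling)
}

# Trial schedule: door open, bell-shaped reach, grasp, lifts, reward.
# Global-burst overlap with the movement extends the trial (slowdown).
schedule_trials <- function(config, global_events) {
  dur <- config$session_duration
  slots <- c("pinch", "key", "cylinder", "tripod")
  starts <- seq(2, dur - config$trial_gap, by = config$trial_gap)
  rows <- lapply(seq_along(starts), function(i) {
    door <- starts[i] + stats::runif(1, 0, 0.5)
    tc <- door + 0.8 + stats::runif(1, 0, 0.4)       # speed-peak time
    w <- 0.20 + stats::runif(1, -0.02, 0.02)          # bell width
    half <- w * sqrt(2 * log(10))                     # 0.1 x peak half-width
    reach_start <- tc - half
    grasp_start <- tc + half
    grasp_base <- 1.2 + stats::runif(1, 0, 0.8)
    # slowdowns stretch the manipulation phase
    ov <- 0
    if (nrow(global_events)) {
      s <- pmax(global_events$start_s, reach_start)
      e <- pmin(global_events$end_s, grasp_start + grasp_base)
      ov <- sum(pmax(0, e - s))
    }
    first_lift <- grasp_start + 0.5 * grasp_base
    last_lift <- grasp_start + grasp_base + 2 * ov
    rewarded <- stats::runif(1) < 0.9
    reward_time <- if (rewarded) last_lift + 0.267 else NA_real_
    data.frame(trial = i, slot = sample(slots, 1), rewarded = rewarded,
               door_open = door, reach_start = reach_start,
               grasp_start = grasp_start, peak_time = tc, bell_width = w,
               first_lift = first_lift, last_lift = last_lift,
               reward_time = reward_time)
  })
  do.call(rbind, rows)
}

#' Generate reach-to-grasp hand kinematics
#'
#' One bell-shaped (Gaussian) speed profile per reach, low-amplitude
#' manipulation movement during the grasp phase, zero speed otherwise. Speed
#' is multiplied by `slowdown_factor` inside slowdown intervals. Positions
#' integrate speed; the apparatus crossing line sits at the mid-reach
#' position.
#'
#' The hand position is cumulative: it advances along a bell-shaped speed
#' profile during each reach, oscillates gently during the grasp
#' (manipulation movement), and holds still between trials, so the trace has
#' no artificial jumps. The apparatus crossing line for a trial sits at the
#' position reached halfway through an unperturbed reach, expressed as a
#' fixed offset from the trial's door-open position.
#'
#' @param trials Trial table from the scheduler (needs `door_open`,
#'   `peak_time`, `bell_width`, `grasp_start`, `last_lift`).
#' @param slowdowns `data.frame(start_s, end_s)` slowdown intervals.
#' @param config A [synth_config()].
#' @return List: `frames` data.frame(time_s, x_mm, y_mm), `crossing_offset`
#'   mm (crossing line relative to door-open position), `peak_speed` mm/s.
#' @export
generate_trial_kinematics <- function(trials, slowdowns, config) {
  fr <- config$frame_rate
  tt <- seq(0, config$session_duration, by = 1 / fr)
  slow <- rep(1, length(tt))
  if (!is.null(slowdowns) && nrow(slowdowns))
    for (i in seq_len(nrow(slowdowns))) {
      idx <- tt >= slowdowns$start_s[i] & tt < slowdowns$end_s[i]
      slow[idx] <- config$slowdown_factor
    }
  vmax <- 300                                    # mm/s nominal peak speed
  x <- rep(0, length(tt))
  pos <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    reach <- which(tt >= tr$door_open & tt <= tr$grasp_start)
    v <- vmax * exp(-0.5 * ((tt[reach] - tr$peak_time) / tr$bell_width)^2) *
      slow[reach]
    xr <- pos + (cumsum(v) - (v[1] + v) / 2) / fr   # trapezoidal integral
    x[reach] <- xr
    pos_grasp <- if (length(xr)) xr[length(xr)] else pos
    grasp <- which(tt > tr$grasp_start & tt <= tr$last_lift)
    if (length(grasp))
      x[grasp] <- pos_grasp +
        2 * slow[grasp] * sin(2 * pi * 2 * (tt[grasp] - tr$grasp_start))
    pos <- if (length(grasp)) x[grasp[length(grasp)]] else pos_grasp
    hold <- which(tt > tr$last_lift &
                    (i == nrow(trials) | tt < trials$door_open[min(i + 1, nrow(trials))]))
    x[hold] <- pos
  }
  # crossing line: mid-reach displacement of an unperturbed bell
  reach_span <- vmax * trials$bell_width[1] * sqrt(2 * pi)
  frames <- data.frame(time_s = tt, x_mm = x, y_mm = 0)
  list(frames = frames, crossing_offset = reach_span / 2, peak_speed = vmax)
}

#' Generate one complete synthetic session with ground truth
#'
#' @param config A [synth_config()].
#' @return List of two elements: `bundle` (a `session_bundle`: LFP matrices,
#'   geometry, spikes, waveforms, trial table, kinematics, rates) and
#'   `truth` (burst events with channel membership, spike coupling, trial
#'   events, slowdown intervals).
#' @examples
#' out <- generate_session(synth_config(session_duration = 20, seed = 2))
#' nrow(out$truth$burst_events)
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- floor(config$session_duration * config$fs_raw)
  events <- schedule_burst_events(config)

  cortex <- pink_noise_matrix(n, config$n_cortical_channels, config$fs_raw,
                              config$noise_exponent, config$common_mode)
  subcx <- pink_noise_matrix(n, config$n_subcortical_channels, config$fs_raw,
                             config$noise_exponent, config$common_mode)
  cortex <- inject_bursts(cortex, events, config$fs_raw)
  # coincident subcortical bursts
  sub_events <- events[events$subcortical %in% TRUE, , drop = FALSE]
  if (nrow(sub_events)) {
    # the subcortical probe sits in one nucleus: coincident bursts span it
    sub_events$channels <- I(rep(list(seq_len(config$n_subcortical_channels)),
                                 nrow(sub_events)))
    subcx <- inject_bursts(subcx, sub_events, config$fs_raw)
  }

  sp <- generate_entrained_spikes(events, config)
  wf <- synth_waveforms(config$n_units)

  glob <- events[events$class == "global", , drop = FALSE]
  trials <- schedule_trials(config, glob)
  slowdowns <- if (nrow(glob))
    data.frame(start_s = glob$start_s, end_s = glob$end_s)
  else data.frame(start_s = numeric(0), end_s = numeric(0))
  kin <- generate_trial_kinematics(trials, slowdowns, config)

  # pre-stroke per-slot normalization table (generator metadata)
  prestroke <- data.frame(slot = c("pinch", "key", "cylinder", "tripod"),
                          mean_reach_s = 0.55, mean_grasp_s = 1.0,
                          mean_trial_s = 1.8)

  bundle <- structure(list(
    session_id = sprintf("synth-seed%d", config$seed),
    lfp_cortex = cortex, lfp_subcortex = subcx, fs_raw = config$fs_raw,
    geometry = grid_geometry(config$n_cortical_channels,
                             config$x_spacing, config$y_spacing),
    spikes = sp$spikes, waveforms = wf,
    trials = trials, kinematics = kin$frames,
    crossing_offset = kin$crossing_offset,
    frame_rate = config$frame_rate, beta_band = config$beta_band,
    prestroke = prestroke), class = "session_bundle")
  truth <- structure(list(
    burst_events = events, spike_coupling = sp$coupling,
    trial_events = trials, slowdown_intervals = slowdowns,
    config = config), class = "session_truth")
  list(bundle = bundle, truth = truth)
}

# plausible average spike waveforms + per-sample SD for SNR bookkeeping
synth_waveforms <- function(n_units, n_samp = 40) {
  t <- seq_len(n_samp)
  mean_wf <- sapply(seq_len(n_units), function(u) {
    trough <- -(4 + u %% 3) * exp(-0.5 * ((t - 14) / 2.2)^2)
    peak <- (2 + 0.3 * u) * exp(-0.5 * ((t - 22) / 3.5)^2)
    trough + peak
  })
  list(mean = mean_wf, sd = matrix(1, n_samp, n_units))
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle %s: %d cortical + %d subcortical channels, %.1f s @ %.1f Hz, %d units, %d trials>\n",
              x$session_id, ncol(x$lfp_cortex), ncol(x$lfp_subcortex),
              nrow(x$lfp_cortex) / x$fs_raw, x$fs_raw, length(x$spikes),
              nrow(x$trials)))
  invisible(x)
}
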