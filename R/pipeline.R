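# End-to-end orchestration over one or more session bundles: preprocess,
# detect per-channel bursts, fit one pooled local/global threshold, segment
# population events, and emit spatial, spiking and behavioral summary
# tables plus a machine-readable run manifest.

#' Pipeline configuration
#'
#' Defaults are the analysis constants used throughout: 100 ms minimum
#' burst duration, 3-channel minimum, 100 shuffles, 50 ms dynamics bins
#' with 200 subsample repetitions, a \[-0.35, 0.35\] s alignment window,
#' the 0.1 x peak speed rule and the 10 s trial timeout.
#'
#' @param beta_band `c(low, high)` Hz (overridden per bundle when the
#'   bundle records its own band).
#' @param filter_order Butterworth prototype order.
#' @param decimation_factor Raw-to-analysis decimation.
#' @param min_burst_dur Minimum burst duration, s.
#' @param min_channels Minimum bursting channels for a cortical burst
#'   timepoint.
#' @param n_shuffles Shuffle repetitions (spatial null and entrainment).
#' @param dynamics_bin Population-dynamics bin, s.
#' @param dynamics_trials,dynamics_units,dynamics_reps Subsample protocol.
#' @param trial_window Trial segmentation window around reach start, s.
#' @param align_window Burst/behavior alignment half-width, s.
#' @param speed_frac Onset/offset fraction of peak speed.
#' @param timeout Trial timeout, s.
#' @param early_late_threshold Recovery-index split.
#' @param exclude_sd_k Automatic channel-exclusion multiplier.
#' @param seed Master seed for all stochastic stages.
#' @export
pipeline_config <- function(beta_band = c(15, 35), filter_order = 3,
                            decimation_factor = 3, min_burst_dur = 0.100,
                            min_channels = 3, n_shuffles = 100,
                            dynamics_bin = 0.050, dynamics_trials = 8,
                            dynamics_units = 12, dynamics_reps = 200,
                            trial_window = c(-3, 10), align_window = 0.35,
                            speed_frac = 0.1, timeout = 10,
                            early_late_threshold = 0.5, exclude_sd_k = 5,
                            seed = 1L) {
  structure(list(beta_band = beta_band, filter_order = filter_order,
                 decimation_factor = decimation_factor,
                 min_burst_dur = min_burst_dur, min_channels = min_channels,
                 n_shuffles = n_shuffles, dynamics_bin = dynamics_bin,
                 dynamics_trials = dynamics_trials,
                 dynamics_units = dynamics_units,
                 dynamics_reps = dynamics_reps, trial_window = trial_window,
                 align_window = align_window, speed_frac = speed_frac,
                 timeout = timeout,
                 early_late_threshold = early_late_threshold,
                 exclude_sd_k = exclude_sd_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preprocess and detect bursts for one session
#'
#' Decimates cortex and subcortex, computes the analytic beta series,
#' applies the automatic noisy-channel rule, computes per-channel
#' thresholds over the union of trial windows, and detects per-channel
#' bursts.
#'
#' @param bundle A `session_bundle`.
#' @param config A [pipeline_config()].
#' @return List with decimated fs, analytic series, detections and masks
#'   for cortex and subcortex, and the channel-fraction series.
#' @export
process_session_lfp <- function(bundle, config = pipeline_config()) {
  band <- if (!is.null(bundle$beta_band)) bundle$beta_band else
    config$beta_band
  ab_c <- beta_series_fft(bundle$lfp_cortex, bundle$fs_raw,
                          config$decimation_factor, band,
                          config$filter_order)
  ab_s <- beta_series_fft(bundle$lfp_subcortex, bundle$fs_raw,
                          config$decimation_factor, band,
                          config$filter_order)
  fs <- ab_c$fs
  n <- nrow(ab_c$amplitude)
  segs <- trial_segments(bundle$trials$reach_start, config$trial_window,
                         fs, n)
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(segs)))
    mask[segs$start_sample[i]:(segs$end_sample[i] - 1)] <- TRUE
  excl <- exclude_noisy_channels(ab_c$amplitude, config$exclude_sd_k)
  det_c <- detect_bursts_all(ab_c, mask, config$min_burst_dur, excl)
  det_s <- detect_bursts_all(ab_s, mask, config$min_burst_dur)
  masks_c <- burst_masks(det_c$events, n, ncol(ab_c$amplitude))
  masks_s <- burst_masks(det_s$events, n, ncol(ab_s$amplitude))
  frac <- fraction_bursting(masks_c, excl)
  list(fs = fs, analytic_cortex = ab_c, analytic_subcortex = ab_s,
       detections_cortex = det_c, detections_subcortex = det_s,
       masks_cortex = masks_c, masks_subcortex = masks_s,
       fraction = frac, excluded = excl, segments = segs,
       trial_mask = mask)
}

#' Run the full pipeline over session bundles
#'
#' One local/global threshold is fitted on the pooled per-session fraction
#' distributions and applied to all sessions. Outputs are written as TSV
#' tables plus a JSON manifest; the run is deterministic given the config
#' seed.
#'
#' @param bundles List of `session_bundle` objects or paths to HDF5
#'   bundles.
#' @param out_dir Results directory (created).
#' @param config A [pipeline_config()].
#' @return Invisible list with the per-session results and the manifest.
#' @export
run_pipeline <- function(bundles, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("betaburst")),
                   seed = config$seed, n_sessions = length(bundles),
                   stages = list())
  if (!length(bundles)) {
    warning("empty session list; writing empty manifest")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(manifest = manifest, sessions = list())))
  }
  bundles <- lapply(bundles, function(b)
    if (is.character(b)) read_session_bundle(b) else b)

  lfp <- lapply(bundles, process_session_lfp, config = config)
  # pooled threshold over all sessions ("for all days")
  fracs <- lapply(lfp, function(s)
    s$fraction$fraction[s$fraction$count >= config$min_channels])
  thr <- fit_local_global_threshold(fracs)

  sessions <- list()
  all_events <- list()
  for (k in seq_along(bundles)) {
    b <- bundles[[k]]; s <- lfp[[k]]
    seg <- label_and_segment(s$fraction, thr, s$masks_cortex, s$fs,
                             config$min_channels, config$min_burst_dur)
    cooc <- subcortical_cooccurrence(seg$events, s$masks_subcortex)
    epochs <- define_epochs(b$trials, config$timeout)
    det_beh <- detect_session_events(b$kinematics, b$trials,
                                     b$crossing_offset, b$frame_rate)
    sp <- hand_speed(b$kinematics$x_mm, NULL, b$frame_rate)
    speed_cat <- speed_by_burst_category(
      sp, b$kinematics$time_s, seg$labels, s$fs,
      rbind(epochs$reach, epochs$grasp))
    align <- do.call(rbind, lapply(c("local", "global"), function(cat)
      data.frame(session = b$session_id, category = cat,
                 event = "grasp_start",
                 fraction = align_burst_fraction(
                   seg$events, b$trials$grasp_start,
                   config$align_window, cat))))
    occ <- do.call(rbind, lapply(c("local", "global"), function(cat) {
      o <- burst_occupancy_vs_trial_time(seg$events, b$trials, b$prestroke,
                                         cat)
      if (nrow(o)) cbind(session = b$session_id, category = cat, o) else NULL
    }))

    # spatial clustering per category over reach+grasp events
    spatial <- do.call(rbind, lapply(c("local", "global"), function(cat) {
      in_move <- rep(FALSE, length(seg$labels))
      for (ep in list(epochs$reach, epochs$grasp))
        for (i in seq_len(nrow(ep))) {
          i0 <- max(1L, floor(ep$start[i] * s$fs) + 1L)
          i1 <- min(length(in_move), floor(ep$end[i] * s$fs))
          if (i1 >= i0) in_move[i0:i1] <- TRUE
        }
      sel <- seg$events$category == cat &
        in_move[seg$events$start_sample]     # epoch of the event onset
      if (!any(sel)) return(NULL)
      ss <- spatial_summary(seg$events[sel, , drop = FALSE],
                            seg$fracact[sel, , drop = FALSE],
                            s$masks_cortex, b$geometry,
                            config$n_shuffles, config$seed + k)
      if (nrow(ss)) cbind(session = b$session_id, category = cat, ss)
      else NULL
    }))

    # spiking stages
    incl <- unit_inclusion(b$spikes, b$waveforms,
                           nrow(b$lfp_cortex) / b$fs_raw)
    units <- b$spikes[incl$included]
    firing <- do.call(rbind, lapply(names(units), function(u) {
      st <- epoch_firing_stats(units[[u]], epochs$grasp)
      bc <- burst_conditioned_firing(units[[u]], seg$labels, s$fs,
                                     epochs$grasp)
      cbind(session = b$session_id, unit = u,
            grasp_rate = st$mean_rate, grasp_var = st$variability, bc)
    }))
    # population dynamics: 50 ms bins, 0.5 s before reach start to first
    # lift, random trial/unit subsamples; skipped (with a manifest note)
    # when the session is smaller than the subsample protocol
    dyn <- NULL; dyn_cat <- NULL
    tr_ok <- b$trials[!is.na(b$trials$reach_start) &
                        !is.na(b$trials$first_lift), , drop = FALSE]
    tr_ok <- tr_ok[tr_ok$first_lift - (tr_ok$reach_start - 0.5) >=
                     2 * config$dynamics_bin, , drop = FALSE]
    if (nrow(tr_ok) > config$dynamics_trials &&
        length(units) >= config$dynamics_units) {
      trial_bins <- lapply(seq_len(nrow(tr_ok)), function(i) {
        s0 <- tr_ok$reach_start[i] - 0.5
        s1 <- tr_ok$first_lift[i]
        sapply(units, function(st)
          bin_spikes(st, s0, s1, config$dynamics_bin) / config$dynamics_bin)
      })
      dyn <- dynamics_subsample(trial_bins, config$dynamics_trials,
                                config$dynamics_units,
                                config$dynamics_reps, config$seed + k)
      write_tsv(dyn, file.path(out_dir,
                               sprintf("dynamics_%s.tsv", b$session_id)))
      # per-trial per-category R2 from one fit on the first trials
      train <- seq_len(config$dynamics_trials)
      test <- setdiff(seq_along(trial_bins), train)
      mod <- fit_dynamics_model(trial_bins, train)
      preds <- lapply(trial_bins[test], predict_dynamics, model = mod)
      conds <- lapply(test, function(i)
        bin_condition(seg$labels, s$fs, tr_ok$reach_start[i] - 0.5,
                      tr_ok$first_lift[i], config$dynamics_bin))
      dyn_cat <- category_predictability(trial_bins[test], preds, conds)
      dyn_cat$trial <- tr_ok$trial[test][dyn_cat$trial]
      write_tsv(dyn_cat, file.path(out_dir,
                                   sprintf("dynamics_r2_%s.tsv",
                                           b$session_id)))
    }
    sessions[[b$session_id]] <- list(
      threshold = thr, events = seg$events, labels = seg$labels,
      fracact = seg$fracact, cooccurrence = cooc, behavior_events = det_beh,
      spatial = spatial, alignment = align, occupancy = occ,
      speed = speed_cat$means, firing = firing, inclusion = incl,
      dynamics = dyn, dynamics_categories = dyn_cat,
      fs = s$fs, excluded = s$excluded)
    ev <- cbind(session = b$session_id,
                seg$events[, c("category", "start_s", "end_s", "duration_s")])
    all_events[[k]] <- ev
    write_tsv(ev, file.path(out_dir, sprintf("events_%s.tsv", b$session_id)))
    write_tsv(cooc, file.path(out_dir,
                              sprintf("cooccurrence_%s.tsv", b$session_id)))
    if (!is.null(spatial))
      write_tsv(spatial, file.path(out_dir,
                                   sprintf("spatial_%s.tsv", b$session_id)))
    write_tsv(firing, file.path(out_dir,
                                sprintf("firing_%s.tsv", b$session_id)))
    write_tsv(det_beh, file.path(out_dir,
                                 sprintf("behavior_%s.tsv", b$session_id)))
    manifest$stages[[b$session_id]] <-
      list(n_channel_bursts = nrow(s$detections_cortex$events),
           n_population_events = nrow(seg$events),
           n_excluded_channels = length(s$excluded),
           n_included_units = sum(incl$included),
           dynamics = if (is.null(dyn)) "skipped: below subsample minimums"
                      else sprintf("mean held-out R2 %.3f", mean(dyn$r2)))
  }
  manifest$threshold <- thr$threshold
  manifest$mixture <- list(weights = thr$weights, means = thr$means,
                           sds = thr$sds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, sessions = sessions,
                 threshold = thr))
}
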