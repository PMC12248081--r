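# Spiking analyses: unit inclusion (SNR, rate), epoch and burst-conditioned
# firing statistics, spike-phase entrainment with a rate-matched shuffle
# null, entrainment/rate-change association, and one-step linear
# population-dynamics predictability split by burst category.

#' Waveform signal-to-noise ratio
#'
#' Peak minus trough of the average waveform divided by the SD of the
#' average-waveform samples outside an exclusion window spanning slightly
#' before the trough to slightly after the peak.
#'
#' @param mean_wf Average waveform (numeric vector).
#' @param exclude Optional integer index window to exclude from the noise
#'   SD; by default the trough-to-peak region padded by 2 samples.
#' @param pad Padding (samples) around the trough/peak region.
#' @return SNR (dimensionless).
#' @export
unit_snr <- function(mean_wf, exclude = NULL, pad = 2L) {
  stopifnot(length(mean_wf) >= 3)
  if (is.null(exclude)) {
    lo <- max(1L, min(which.min(mean_wf), which.max(mean_wf)) - pad)
    hi <- min(length(mean_wf), max(which.min(mean_wf), which.max(mean_wf)) + pad)
    exclude <- lo:hi
  }
  tail_idx <- setdiff(seq_along(mean_wf), exclude)
  if (!length(tail_idx)) stop("exclusion window covers all samples")
  noise <- stats::sd(mean_wf[tail_idx])
  if (noise == 0) return(if (max(mean_wf) == min(mean_wf)) 0 else Inf)
  (max(mean_wf) - min(mean_wf)) / noise
}

#' Unit inclusion table
#'
#' A unit is included iff SNR > 3 and its mean session firing rate exceeds
#' 0.5 Hz.
#'
#' @param spikes Named list of spike-time vectors.
#' @param waveforms List with `mean` (samples x units matrix).
#' @param session_duration Session length, s.
#' @return `data.frame(unit, snr, mean_rate_hz, included)`.
#' @export
unit_inclusion <- function(spikes, waveforms, session_duration) {
  data.frame(
    unit = names(spikes),
    snr = vapply(seq_along(spikes),
                 function(u) unit_snr(waveforms$mean[, u]), 0),
    mean_rate_hz = vapply(spikes, length, 0L) / session_duration,
    included = vapply(seq_along(spikes), function(u)
      unit_snr(waveforms$mean[, u]) > 3 &&
        length(spikes[[u]]) / session_duration > 0.5, TRUE),
    row.names = NULL)
}

# spike counts in fixed-width bins over [start, end); drops the ragged tail
bin_spikes <- function(times, start, end, bin) {
  n_bins <- floor((end - start) / bin)
  if (n_bins < 1) return(NULL)
  t <- times[times >= start & times < start + n_bins * bin]
  idx <- floor((t - start) / bin) + 1
  tabulate(idx, nbins = n_bins)
}

#' Trial-averaged epoch firing rate and variability
#'
#' Rates from 10 ms bins within each epoch; per-trial mean rate and rate SD
#' (the variability), averaged across trials. Epochs shorter than one bin
#' are skipped with a warning.
#'
#' @param times Spike times (s) of one unit.
#' @param epochs `data.frame(start, end)` of per-trial epoch intervals, s.
#' @param bin Bin width, s (default 0.010).
#' @return `list(mean_rate, variability, n_trials)`.
#' @export
epoch_firing_stats <- function(times, epochs, bin = 0.010) {
  if (!nrow(epochs)) stop("no epochs supplied")
  rates <- vars <- numeric(0)
  for (i in seq_len(nrow(epochs))) {
    cnt <- bin_spikes(times, epochs$start[i], epochs$end[i], bin)
    if (is.null(cnt)) {
      warning(sprintf("epoch %d shorter than one bin; skipped", i))
      next
    }
    r <- cnt / bin
    rates <- c(rates, mean(r))
    vars <- c(vars, if (length(r) > 1) stats::sd(r) else 0)
  }
  list(mean_rate = if (length(rates)) mean(rates) else NA_real_,
       variability = if (length(vars)) mean(vars) else NA_real_,
       n_trials = length(rates))
}

# majority burst-category label for each bin; ties go to the lower code
bin_condition <- function(labels, fs, start, end, bin) {
  n_bins <- floor((end - start) / bin)
  if (n_bins < 1) return(integer(0))
  vapply(seq_len(n_bins), function(k) {
    t0 <- start + (k - 1) * bin; t1 <- start + k * bin
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(length(labels), ceiling(t1 * fs))
    if (i1 < i0) return(0L)
    tab <- tabulate(labels[i0:i1] + 1L, nbins = 3)
    as.integer(which.max(tab) - 1L)   # which.max takes the first (lowest) tie
  }, 0L)
}

#' Burst-conditioned firing statistics
#'
#' Splits each epoch's 10 ms bins into no-burst / local / global conditions
#' by majority label within the bin and reports per-condition mean rate and
#' rate variability, trial-averaged. Trials contributing no bins to a
#' condition are ignored for that condition.
#'
#' @param times Spike times of one unit, s.
#' @param labels Per-sample 0/1/2 labels on the LFP grid.
#' @param fs LFP sampling rate, Hz.
#' @param epochs `data.frame(start, end)` epochs (typically grasping).
#' @param bin Bin width, s.
#' @return `data.frame(condition, mean_rate, variability, n_trials)` with
#'   conditions `none`, `local`, `global`.
#' @export
burst_conditioned_firing <- function(times, labels, fs, epochs, bin = 0.010) {
  acc <- list(none = list(r = c(), v = c()), local = list(r = c(), v = c()),
              global = list(r = c(), v = c()))
  cats <- c("none", "local", "global")
  for (i in seq_len(nrow(epochs))) {
    cnt <- bin_spikes(times, epochs$start[i], epochs$end[i], bin)
    if (is.null(cnt)) next
    cond <- bin_condition(labels, fs, epochs$start[i], epochs$end[i], bin)
    r <- cnt / bin
    for (k in 0:2) {
      sel <- cond == k
      if (!any(sel)) next
      nm <- cats[k + 1]
      acc[[nm]]$r <- c(acc[[nm]]$r, mean(r[sel]))
      acc[[nm]]$v <- c(acc[[nm]]$v,
                       if (sum(sel) > 1) stats::sd(r[sel]) else 0)
    }
  }
  do.call(rbind, lapply(cats, function(nm) data.frame(
    condition = nm,
    mean_rate = if (length(acc[[nm]]$r)) mean(acc[[nm]]$r) else NA_real_,
    variability = if (length(acc[[nm]]$v)) mean(acc[[nm]]$v) else NA_real_,
    n_trials = length(acc[[nm]]$r))))
}

#' Resultant vector length of a set of phases
#'
#' @param phases Phases in radians.
#' @return `r` in `[0, 1]`; `NA` for an empty set.
#' @export
resultant_length <- function(phases) {
  if (!length(phases)) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Spike-phase entrainment with rate-matched shuffle null
#'
#' For each unit and LFP channel: collect the channel's beta phase at every
#' spike that falls inside a burst event of the given class (and inside the
#' behavioral epoch), compute the resultant vector length `r`, and calibrate
#' it against `n_shuffles` draws of the same number of phases (with
#' replacement) from the channel's pooled in-burst in-epoch phase samples.
#' Significance: `r` above the 95th percentile of the shuffle distribution;
#' modulation z-score: `(r - shuffle mean) / shuffle SD`.
#'
#' @param spikes Named list of spike-time vectors, s.
#' @param phase Samples-by-channels phase matrix (radians).
#' @param fs LFP sampling rate, Hz.
#' @param events Burst event table of one category (`start_s`, `end_s`).
#' @param epochs Optional `data.frame(start, end)` restricting to a
#'   behavioral epoch; `NULL` uses the whole session.
#' @param n_shuffles Number of shuffle draws (default 100).
#' @param seed RNG seed for the shuffles.
#' @return `data.frame(unit, channel, n_spikes, r, shuffle_mean,
#'   shuffle_sd, z, significant)`; rows with `n_spikes = 0` carry `NA`
#'   statistics (undefined, not zero).
#' @export
phase_entrainment <- function(spikes, phase, fs, events, epochs = NULL,
                              n_shuffles = 100, seed = 1L) {
  if (!nrow(events)) stop("no burst events supplied")
  n <- nrow(phase)
  in_burst <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start_s[i] * fs) + 1L)
    i1 <- min(n, floor(events$end_s[i] * fs))
    if (i1 >= i0) in_burst[i0:i1] <- TRUE
  }
  if (!is.null(epochs)) {
    in_ep <- rep(FALSE, n)
    for (i in seq_len(nrow(epochs))) {
      i0 <- max(1L, floor(epochs$start[i] * fs) + 1L)
      i1 <- min(n, floor(epochs$end[i] * fs))
      if (i1 >= i0) in_ep[i0:i1] <- TRUE
    }
    in_burst <- in_burst & in_ep
  }
  pool_idx <- which(in_burst)
  set.seed(seed)
  res <- list()
  for (u in seq_along(spikes)) {
    # 1 ms binning of spike times, then map to LFP sample indices
    st <- floor(spikes[[u]] * 1000) / 1000 + 5e-4
    sidx <- floor(st * fs) + 1L
    sidx <- sidx[sidx >= 1 & sidx <= n]
    sidx <- sidx[in_burst[sidx]]
    ns <- length(sidx)
    for (ch in seq_len(ncol(phase))) {
      if (ns == 0) {
        res[[length(res) + 1]] <- data.frame(
          unit = names(spikes)[u], channel = ch, n_spikes = 0L,
          r = NA_real_, shuffle_mean = NA_real_, shuffle_sd = NA_real_,
          z = NA_real_, significant = NA)
        next
      }
      r <- resultant_length(phase[sidx, ch])
      pool <- phase[pool_idx, ch]
      draws <- matrix(pool[sample.int(length(pool), ns * n_shuffles,
                                      replace = TRUE)], ns, n_shuffles)
      rs <- Mod(colMeans(exp(1i * draws)))
      res[[length(res) + 1]] <- data.frame(
        unit = names(spikes)[u], channel = ch, n_spikes = ns, r = r,
        shuffle_mean = mean(rs), shuffle_sd = stats::sd(rs),
        z = (r - mean(rs)) / stats::sd(rs),
        significant = r > stats::quantile(rs, 0.95))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Association between entrainment and burst-related firing changes
#'
#' Per unit: the median modulation z-score across its significantly
#' entrained channels, paired with the unit's firing-rate and variability
#' differences between burst and non-burst grasp bins. Units with no
#' significant channel are excluded. An OLS fit of each delta on the median
#' z is reported as a descriptive summary.
#'
#' @param entrain Output of [phase_entrainment()].
#' @param deltas `data.frame(unit, delta_rate, delta_variability)`.
#' @return List: `table` (unit, median_z, delta_rate, delta_variability),
#'   `fit_rate` and `fit_variability` (slope, t, p), possibly `NULL` when
#'   fewer than 3 units qualify.
#' @export
entrainment_rate_association <- function(entrain, deltas) {
  sig <- entrain[!is.na(entrain$significant) & entrain$significant, ,
                 drop = FALSE]
  if (!nrow(sig))
    return(list(table = data.frame(unit = character(0), median_z = numeric(0),
                                   delta_rate = numeric(0),
                                   delta_variability = numeric(0)),
                fit_rate = NULL, fit_variability = NULL))
  med <- stats::aggregate(z ~ unit, data = sig, FUN = stats::median)
  names(med)[2] <- "median_z"
  tab <- merge(med, deltas, by = "unit")
  ols <- function(y) {
    if (nrow(tab) < 3 || !stats::sd(tab$median_z)) return(NULL)
    f <- stats::lm(y ~ median_z, data = tab)
    s <- summary(f)$coefficients
    c(slope = s[2, 1], t = s[2, 3], p = s[2, 4])
  }
  list(table = tab, fit_rate = ols(tab$delta_rate),
       fit_variability = ols(tab$delta_variability))
}

#' Fit a one-step linear population-dynamics model
#'
#' `X_t = A X_(t-1)` fitted by least squares on stacked consecutive-bin
#' pairs within trials (no cross-trial pairs).
#'
#' @param trial_bins List of bins-by-units rate matrices, one per trial.
#' @param train Indices of training trials.
#' @return List: `A` (units x units), `train`, `n_units`.
#' @export
fit_dynamics_model <- function(trial_bins, train = seq_along(trial_bins)) {
  stopifnot(length(train) >= 1)
  Xp <- do.call(rbind, lapply(trial_bins[train], function(m)
    m[-nrow(m), , drop = FALSE]))
  Xn <- do.call(rbind, lapply(trial_bins[train], function(m)
    m[-1, , drop = FALSE]))
  if (nrow(Xp) < ncol(Xp)) stop("fewer bin pairs than units")
  # Xn ~ Xp %*% t(A)
  At <- qr.solve(Xp, Xn)
  list(A = t(At), train = train, n_units = ncol(Xp))
}

#' One-step-ahead predictions for a trial
#'
#' Teacher forcing: each bin is predicted from the true previous bin. The
#' first bin has no prediction.
#'
#' @param model Output of [fit_dynamics_model()].
#' @param bins Bins-by-units matrix for one trial.
#' @return Matrix of predictions for bins `2..n` (rows `n - 1`).
#' @export
predict_dynamics <- function(model, bins) {
  bins[-nrow(bins), , drop = FALSE] %*% t(model$A)
}

#' Held-out one-step R-squared
#'
#' @param model Output of [fit_dynamics_model()].
#' @param trial_bins List of trial matrices.
#' @param test Trial indices to evaluate.
#' @return Pooled R-squared over all held-out one-step predictions.
#' @export
dynamics_r2 <- function(model, trial_bins, test) {
  truth <- do.call(rbind, lapply(trial_bins[test], function(m)
    m[-1, , drop = FALSE]))
  pred <- do.call(rbind, lapply(trial_bins[test], function(m)
    predict_dynamics(model, m)))
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sst
}

#' Repeated random-subsample dynamics fitting
#'
#' Mirrors the fixed-budget protocol: each repetition randomly subselects
#' `n_trials` training trials and `n_units` units, fits the model, and
#' predicts the held-out trials one step ahead.
#'
#' @param trial_bins List of bins-by-units matrices (all candidate units).
#' @param n_trials,n_units Subsample sizes (must not exceed availability).
#' @param n_reps Repetitions (default 200).
#' @param seed RNG seed.
#' @return `data.frame(rep, r2)` plus list-columns are avoided; models are
#'   not retained.
#' @export
dynamics_subsample <- function(trial_bins, n_trials, n_units, n_reps = 200,
                               seed = 1L) {
  n_tr <- length(trial_bins)
  n_u <- ncol(trial_bins[[1]])
  if (n_tr <= n_trials || n_u < n_units)
    stop("fewer trials/units available than the subsample sizes")
  set.seed(seed)
  res <- lapply(seq_len(n_reps), function(r) {
    tr <- sample.int(n_tr, n_trials)
    un <- sample.int(n_u, n_units)
    sub <- lapply(trial_bins, function(m) m[, un, drop = FALSE])
    mod <- fit_dynamics_model(sub, tr)
    data.frame(rep = r, r2 = dynamics_r2(mod, sub, setdiff(seq_len(n_tr), tr)))
  })
  do.call(rbind, res)
}

#' Per-trial per-category predictability
#'
#' For each trial, bins inside the epoch are assigned a burst condition by
#' majority label; per category, `R2 = 1 - SSE/SST` over that trial's bins
#' of that category (SST about the mean of those same true bins, pooled
#' over units). Categories with fewer than `min_bins` bins in a trial, or
#' zero variance, yield `NA` (the trial is not "valid" for that category).
#'
#' @param true_bins,pred_bins Lists (per trial) of aligned bins-by-units
#'   matrices; `pred_bins[[i]]` has one fewer row (no first-bin prediction).
#' @param bin_conditions List (per trial) of per-bin 0/1/2 conditions
#'   aligned with `true_bins` rows.
#' @param min_bins Minimum bins per category per trial (default 2).
#' @return `data.frame(trial, category, r2, n_bins)`.
#' @export
category_predictability <- function(true_bins, pred_bins, bin_conditions,
                                    min_bins = 2) {
  cats <- c("none", "local", "global")
  res <- list()
  for (i in seq_along(true_bins)) {
    tr <- true_bins[[i]][-1, , drop = FALSE]   # align with one-step preds
    pr <- pred_bins[[i]]
    cond <- bin_conditions[[i]][-1]
    stopifnot(nrow(tr) == nrow(pr), length(cond) == nrow(tr))
    for (k in 0:2) {
      sel <- cond == k
      nb <- sum(sel)
      r2 <- NA_real_
      if (nb >= min_bins) {
        y <- tr[sel, , drop = FALSE]; p <- pr[sel, , drop = FALSE]
        sst <- sum((y - mean(y))^2)
        if (sst > 0) r2 <- 1 - sum((y - p)^2) / sst
      }
      res[[length(res) + 1]] <- data.frame(trial = i, category = cats[k + 1],
                                           r2 = r2, n_bins = nb)
    }
  }
  do.call(rbind, res)
}
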