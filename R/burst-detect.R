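# Per-channel beta-burst detection with the dual-threshold rule:
# the envelope must stay above its session median (Thresh) for at least
# 100 ms and the run maximum must exceed median + SD (Thresh2).

#' Per-channel envelope thresholds
#'
#' For each channel, over the session's artifact-free samples: `sigma` is
#' the envelope SD (population, divisor n), `thresh` the envelope median,
#' and `thresh2 = thresh + sigma`.
#'
#' @param amplitude Envelope matrix (samples x channels) or vector.
#' @param sample_mask Optional logical vector marking samples to include
#'   (e.g. the union of trial windows); default all.
#' @return `data.frame(channel, sigma, thresh, thresh2)`.
#' @export
compute_channel_thresholds <- function(amplitude, sample_mask = NULL) {
  if (!is.matrix(amplitude)) amplitude <- matrix(amplitude, ncol = 1)
  if (nrow(amplitude) < 2) stop("need at least 2 samples per channel")
  if (!is.null(sample_mask)) {
    stopifnot(length(sample_mask) == nrow(amplitude))
    amplitude <- amplitude[sample_mask, , drop = FALSE]
  }
  res <- lapply(seq_len(ncol(amplitude)), function(j) {
    a <- amplitude[, j]
    a <- a[!is.na(a)]
    if (!length(a)) stop(sprintf("channel %d is all-NaN", j))
    sigma <- stats::sd(a) * sqrt((length(a) - 1) / length(a))  # population SD
    med <- stats::median(a)
    data.frame(channel = j, sigma = sigma, thresh = med,
               thresh2 = med + sigma)
  })
  do.call(rbind, res)
}

# maximal runs of TRUE in a logical vector -> (start, end) half-open, 1-based
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect burst events on one channel
#'
#' Maximal runs of `envelope > thresh` kept iff the run lasts at least
#' `min_dur` seconds and its envelope maximum exceeds `thresh2`. Spans are
#' half-open in samples and reported in seconds from the start of the
#' series. No gap-bridging is performed.
#'
#' @param envelope Envelope vector for one channel.
#' @param thresh,thresh2 Channel thresholds (see
#'   [compute_channel_thresholds()]).
#' @param fs Sampling rate, Hz.
#' @param min_dur Minimum duration, s (default 0.100; ties at exactly the
#'   minimum are kept).
#' @return `data.frame(start_sample, end_sample, start_s, end_s)`
#'   (half-open; `end_s = end_sample / fs`).
#' @export
detect_channel_bursts <- function(envelope, thresh, thresh2, fs,
                                  min_dur = 0.100) {
  if (fs <= 0) stop("fs must be positive")
  runs <- logical_runs(!is.na(envelope) & envelope > thresh)
  if (!nrow(runs))
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  keep <- logical(nrow(runs))
  long_enough <- (runs[, "end"] - runs[, "start"]) / fs >= min_dur
  for (i in which(long_enough))
    keep[i] <- max(envelope[runs[i, "start"]:(runs[i, "end"] - 1)]) > thresh2
  runs <- runs[keep, , drop = FALSE]
  data.frame(start_sample = as.integer(runs[, "start"]),
             end_sample = as.integer(runs[, "end"]),
             start_s = (runs[, "start"] - 1) / fs,
             end_s = (runs[, "end"] - 1) / fs)
}

#' Burst features for one detected event span
#'
#' Normalized amplitude `(mean in-span envelope - thresh) / sigma`,
#' duration in seconds, and mean frequency as the average in-span
#' instantaneous frequency (`dphase * fs / (2*pi)`).
#'
#' @param start_sample,end_sample Half-open sample span.
#' @param envelope,phase Full per-channel envelope and phase vectors (the
#'   instantaneous frequency is differentiated on the full series, then
#'   averaged over the span).
#' @param thresh,sigma Channel threshold and envelope SD.
#' @param fs Sampling rate, Hz.
#' @return One-row `data.frame(norm_amplitude, duration_s, mean_freq_hz)`;
#'   `norm_amplitude` is `NA` (with a warning) when `sigma == 0`.
#' @export
compute_burst_features <- function(start_sample, end_sample, envelope, phase,
                                   thresh, sigma, fs) {
  idx <- start_sample:(end_sample - 1)
  stopifnot(length(idx) >= 1, end_sample <= length(envelope) + 1)
  na <- if (sigma > 0) (mean(envelope[idx]) - thresh) / sigma else {
    warning("sigma is 0; normalized amplitude undefined")
    NA_real_
  }
  instf <- instantaneous_frequency(phase, fs)
  data.frame(norm_amplitude = na,
             duration_s = length(idx) / fs,
             mean_freq_hz = mean(instf[idx]))
}

#' Detect and featurize bursts on every channel
#'
#' Convenience wrapper: thresholds, detection and features for all channels
#' of an [analytic_beta()] series.
#'
#' @param ab An `analytic_beta` object.
#' @param sample_mask Optional logical inclusion mask for threshold
#'   computation.
#' @param min_dur Minimum burst duration, s.
#' @param exclude_channels Channels to drop entirely.
#' @return List: `events` data.frame(channel, start_sample, end_sample,
#'   start_s, end_s, duration_s, norm_amplitude, mean_freq_hz),
#'   `thresholds`, `excluded`.
#' @export
detect_bursts_all <- function(ab, sample_mask = NULL, min_dur = 0.100,
                              exclude_channels = integer(0)) {
  stopifnot(inherits(ab, "analytic_beta"))
  th <- compute_channel_thresholds(ab$amplitude, sample_mask)
  out <- list()
  for (j in seq_len(ncol(ab$amplitude))) {
    if (j %in% exclude_channels) next
    ev <- detect_channel_bursts(ab$amplitude[, j], th$thresh[j],
                                th$thresh2[j], ab$fs, min_dur)
    if (!nrow(ev)) next
    # span means via cumulative sums (same arithmetic as
    # compute_burst_features, vectorized over events)
    csum_env <- c(0, cumsum(ab$amplitude[, j]))
    csum_if <- c(0, cumsum(instantaneous_frequency(ab$phase[, j], ab$fs)))
    len <- ev$end_sample - ev$start_sample
    mean_env <- (csum_env[ev$end_sample] - csum_env[ev$start_sample]) / len
    feats <- data.frame(
      norm_amplitude = if (th$sigma[j] > 0)
        (mean_env - th$thresh[j]) / th$sigma[j] else NA_real_,
      duration_s = len / ab$fs,
      mean_freq_hz = (csum_if[ev$end_sample] - csum_if[ev$start_sample]) / len)
    out[[length(out) + 1]] <- cbind(channel = j, ev, feats)
  }
  events <- if (length(out)) do.call(rbind, out)
  else data.frame(channel = integer(0), start_sample = integer(0),
                  end_sample = integer(0), start_s = numeric(0),
                  end_s = numeric(0), norm_amplitude = numeric(0),
                  duration_s = numeric(0), mean_freq_hz = numeric(0))
  rownames(events) <- NULL
  list(events = events, thresholds = th, excluded = exclude_channels)
}

#' Per-channel burst sample masks
#'
#' @param events Event table from [detect_bursts_all()].
#' @param n_samples,n_channels Mask dimensions.
#' @return Logical matrix (samples x channels), TRUE while bursting.
#' @export
burst_masks <- function(events, n_samples, n_channels) {
  m <- matrix(FALSE, n_samples, n_channels)
  for (i in seq_len(nrow(events)))
    m[events$start_sample[i]:(events$end_sample[i] - 1), events$channel[i]] <- TRUE
  m
}
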