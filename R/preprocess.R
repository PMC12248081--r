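# LFP preprocessing: anti-aliased decimation, trial segmentation, Welch PSD,
# and the band-limited analytic (amplitude, phase) series that the burst
# detector consumes.

#' Decimate a multichannel LFP signal
#'
#' Anti-aliased downsampling: an order-8 Butterworth lowpass at 0.8 of the
#' post-decimation Nyquist is applied zero-phase, then every `factor`-th
#' sample is kept. Output length is `ceiling(n / factor)`.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs_raw Input sampling rate, Hz.
#' @param factor Integer decimation factor (>= 1).
#' @return List with `signal` (same type as `x`) and `fs` (`fs_raw/factor`).
#' @export
decimate_lfp <- function(x, fs_raw, factor) {
  factor <- as.integer(factor)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (factor < 1) stop("decimation factor must be >= 1")
  if (factor >= n) stop("decimation factor must be smaller than signal length")
  if (factor == 1) return(list(signal = x, fs = fs_raw))
  d <- butter_design(8, 0.8 * (fs_raw / 2) / factor, fs_raw, "low")
  y <- filtfilt(d$b, d$a, x)
  keep <- seq(1, n, by = factor)
  out <- if (is.matrix(y)) y[keep, , drop = FALSE] else y[keep]
  list(signal = out, fs = fs_raw / factor)
}

#' Trial segmentation windows
#'
#' Converts per-trial alignment times into half-open sample windows
#' `[start, end)`. Windows that would extend past the session bounds are
#' clipped and flagged, never silently shortened.
#'
#' @param align_times Alignment event time per trial, s from session start.
#' @param window `c(pre, post)` seconds relative to the alignment event
#'   (pre is typically negative).
#' @param fs Sampling rate of the segmented signal, Hz.
#' @param n_samples Session length in samples.
#' @return `data.frame(trial, start_sample, end_sample, clipped)`;
#'   1-based, end exclusive.
#' @export
trial_segments <- function(align_times, window = c(-3, 10), fs, n_samples) {
  stopifnot(window[1] < window[2])
  start <- floor((align_times + window[1]) * fs) + 1
  end <- floor((align_times + window[2]) * fs) + 1
  clipped <- start < 1 | end > n_samples + 1
  data.frame(trial = seq_along(align_times),
             start_sample = pmax(start, 1),
             end_sample = pmin(end, n_samples + 1),
             clipped = clipped)
}

#' Channel- and trial-averaged power spectral density
#'
#' Welch-style average over 4 s windows stepped so that consecutive windows
#' overlap by the configured amount, computed per trial segment and channel
#' and then averaged.
#'
#' @param signal Samples-by-channels matrix (full session).
#' @param fs Sampling rate, Hz.
#' @param segments Optional output of [trial_segments()]; clipped segments
#'   are dropped. `NULL` treats the whole session as one segment.
#' @param win_sec,overlap_sec PSD window and overlap, s.
#' @return `data.frame(freq_hz, power)`.
#' @export
compute_psd <- function(signal, fs, segments = NULL, win_sec = 4,
                        overlap_sec = 1) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1)
  if (is.null(segments))
    segments <- data.frame(trial = 1, start_sample = 1,
                           end_sample = nrow(signal) + 1, clipped = FALSE)
  segments <- segments[!segments$clipped, , drop = FALSE]
  if (!nrow(segments)) stop("no usable trial segments for PSD")
  if (any(segments$end_sample - segments$start_sample < win_sec * fs))
    stop("segment shorter than one PSD window")
  acc <- NULL; nacc <- 0
  for (i in seq_len(nrow(segments))) {
    idx <- segments$start_sample[i]:(segments$end_sample[i] - 1)
    for (j in seq_len(ncol(signal))) {
      p <- welch_psd_vec(signal[idx, j], fs, win_sec, overlap_sec)
      if (is.null(acc)) acc <- p$power else acc <- acc + p$power
      nacc <- nacc + 1
      freq <- p$freq
    }
  }
  data.frame(freq_hz = freq, power = acc / nacc)
}

#' Band-limited analytic amplitude and phase
#'
#' Butterworth bandpass (zero-phase, forward-backward) in the configured
#' beta band followed by the FFT analytic signal. Computed on the full
#' session so trial-window edges carry no transform edge artifacts; the
#' first and last 0.5 s are flagged as unusable edges.
#'
#' @param signal Samples-by-channels matrix (decimated LFP).
#' @param band `c(low, high)` Hz.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth prototype order (3 or 4 by dataset convention;
#'   zero-phase application doubles the effective order).
#' @return Object of class `analytic_beta` with `amplitude` and `phase`
#'   matrices (same shape as input), `fs`, `band`, `order`, and
#'   `edge_samples` (count flagged at each end).
#' @export
analytic_beta <- function(signal, band, fs, order = 3) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("beta band must lie strictly inside (0, fs/2)")
  d <- butter_design(order, band, fs, "pass")
  filt <- filtfilt(d$b, d$a, signal)
  z <- analytic_signal(filt)
  structure(list(amplitude = Mod(z), phase = Arg(z), fs = fs,
                 band = band, order = order,
                 edge_samples = round(0.5 * fs)),
            class = "analytic_beta")
}

# |H(e^{-iw})|^2 of a digital filter (b, a) at angular frequencies w
# (zero-phase forward-backward magnitude response)
zero_phase_response <- function(b, a, w) {
  ew <- exp(-1i * w)
  horner <- function(cf) {
    acc <- rep(cf[1] + 0i, length(w))
    for (c_ in cf[-1]) acc <- acc * ew + c_
    acc
  }
  Mod(horner(b) / horner(a))^2
}

#' Fused spectral decimation + zero-phase beta filtering + analytic signal
#'
#' One FFT pass per channel that applies the squared-magnitude (zero-phase)
#' response of the anti-aliasing lowpass and the Butterworth beta bandpass,
#' retains positive frequencies only (analytic signal) and resamples to the
#' decimated rate by spectral truncation. Away from the session edges this
#' equals running [decimate_lfp()] then [analytic_beta()] (the band lies far
#' below the decimated Nyquist); it is the pipeline's fast path for long
#' multichannel sessions.
#'
#' @param signal Raw samples-by-channels matrix.
#' @param fs_raw Raw sampling rate, Hz.
#' @param factor Integer decimation factor.
#' @param band Beta band `c(low, high)`, Hz.
#' @param order Bandpass Butterworth prototype order.
#' @return An `analytic_beta` object at rate `fs_raw / factor`.
#' @export
beta_series_fft <- function(signal, fs_raw, factor, band, order = 3) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1)
  factor <- as.integer(factor)
  n <- nrow(signal)
  m <- stats::nextn(n, c(2, 3, 5))
  m <- m + (factor - m %% factor) %% factor   # multiple of the factor
  mp <- m %/% factor
  fs <- fs_raw / factor
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("beta band must lie strictly inside (0, fs/2)")
  w <- 2 * pi * (seq_len(mp) - 1) / m        # kept (positive) frequencies
  dlow <- butter_design(8, 0.8 * (fs / 2), fs_raw, "low")
  dband <- butter_design(order, band, fs_raw, "pass")
  resp <- zero_phase_response(dlow$b, dlow$a, w) *
    zero_phase_response(dband$b, dband$a, w)
  resp <- resp * c(1, rep(2, mp - 1))        # analytic-signal doubling
  n_out <- ceiling(n / factor)
  pad <- m - n
  out_amp <- matrix(0, n_out, ncol(signal))
  out_ph <- matrix(0, n_out, ncol(signal))
  for (j in seq_len(ncol(signal))) {
    x <- signal[, j]
    if (pad > 0) x <- c(x, if (pad < n) 2 * x[n] - x[n - seq_len(pad)]
                        else numeric(pad))
    X <- stats::fft(x)
    z <- stats::fft(X[seq_len(mp)] * resp, inverse = TRUE) / m
    z <- z[seq_len(n_out)]
    out_amp[, j] <- Mod(z)
    out_ph[, j] <- Arg(z)
  }
  structure(list(amplitude = out_amp, phase = out_ph, fs = fs,
                 band = band, order = order,
                 edge_samples = round(0.5 * fs)),
            class = "analytic_beta")
}

#' Instantaneous frequency from an analytic phase series
#'
#' Differentiated unwrapped phase scaled to Hz:
#' `inst_freq = dphase * fs / (2 * pi)`. The first sample is repeated so the
#' output has the same length as the phase series.
#'
#' @param phase Phase vector (radians) or samples-by-channels matrix.
#' @param fs Sampling rate, Hz.
#' @return Instantaneous frequency, Hz, same shape as `phase`.
#' @export
instantaneous_frequency <- function(phase, fs) {
  if (is.matrix(phase)) {
    out <- phase
    for (j in seq_len(ncol(phase)))
      out[, j] <- instantaneous_frequency(phase[, j], fs)
    return(out)
  }
  dp <- diff(phase)
  dp <- wrap_pi(dp)      # unwrap: principal value of the phase increment
  f <- dp * fs / (2 * pi)
  c(f[1], f)
}

#' Automatic noisy-channel exclusion
#'
#' Flags channels whose envelope SD exceeds `k` times the median channel
#' envelope SD. Stands in for the manual artifact screening used on real
#' recordings.
#'
#' @param amplitude Envelope matrix (samples x channels).
#' @param k Exclusion multiplier (default 5).
#' @return Integer vector of excluded channel indices (possibly empty).
#' @export
exclude_noisy_channels <- function(amplitude, k = 5) {
  sds <- apply(amplitude, 2, stats::sd)
  which(sds > k * stats::median(sds))
}
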