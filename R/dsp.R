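# Core DSP primitives: Butterworth design via bilinear transform, zero-phase
# IIR filtering, FFT analytic signal, anti-aliased decimation, Welch PSD.
# No signal-processing package is assumed; the IIR recursion runs in C++.

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth filter by the standard analog-prototype +
#' bilinear-transform route and returns transfer-function coefficients.
#'
#' @param order Filter order of the analog prototype. A bandpass design has
#'   digital order `2 * order`.
#' @param cutoff Cutoff frequency in Hz: one value for `type = "low"`, a
#'   `c(low, high)` pair for `type = "pass"`.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"pass"`.
#' @return List with numerator `b` and denominator `a` (leading `a` term 1).
#' @export
butter_design <- function(order, cutoff, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0, all(cutoff > 0), all(cutoff < fs / 2))
  # analog lowpass prototype: poles on the unit circle, no finite zeros
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  gain <- 1
  warp <- function(f) 2 * fs * tan(pi * f / fs)  # bilinear prewarp
  if (type == "low") {
    wc <- warp(cutoff[1])
    p <- p * wc
    gain <- wc^order
    z <- complex(0)
  } else {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2])
      stop("bandpass needs cutoff = c(low, high) with low < high")
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    plp <- p * bw / 2
    p <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
    z <- rep(0 + 0i, order)      # bandpass zeros at s = 0
    gain <- bw^order
  }
  # bilinear transform s -> 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # zeros at analog infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  poly_from_roots <- function(r) {
    c <- 1 + 0i
    for (ri in r) c <- c(c, 0) - c(0, c * ri)
    Re(c)
  }
  list(b = gain * poly_from_roots(zd), a = poly_from_roots(pd))
}

# steady-state initial filter state for a unit-step input (used so filtfilt
# edge transients decay against the first/last sample rather than zero)
filter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[-1]
  if (n > 2) A[cbind(1:(n - 2), 2:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - A, B)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection end padding,
#' cancelling the filter's phase response. Effective magnitude response is
#' the square of the single-pass filter.
#'
#' @param b,a Transfer-function coefficients, e.g. from [butter_design()].
#' @param x Numeric vector, or a samples-by-channels matrix filtered
#'   column-wise.
#' @return Filtered object of the same shape as `x`.
#' @export
filtfilt <- function(b, a, x) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- filtfilt(b, a, x[, j])
    return(x)
  }
  a0 <- a[1]
  b <- b / a0; a <- a / a0
  n <- length(x)
  pad <- 3 * (max(length(a), length(b)) - 1)
  if (n <= pad + 1) stop("signal too short for filtfilt edge padding")
  zi <- filter_zi(b, a)
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(front, x, back)
  y <- .iir_df2t(b, a, xe, zi * xe[1])
  y <- rev(.iir_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal whose modulus is the instantaneous
#' amplitude (envelope) and whose argument is the instantaneous phase.
#' Internally pads to a 5-smooth length by odd reflection for FFT speed,
#' then truncates back.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @return Complex object of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(0i, nrow(x), ncol(x), dimnames = dimnames(x))
    for (j in seq_len(ncol(x))) out[, j] <- analytic_signal(x[, j])
    return(out)
  }
  n <- length(x)
  if (n < 4) stop("signal too short for analytic transform")
  m <- stats::nextn(n, c(2, 3, 5))
  if (m > n && (m - n) < n) {
    xp <- c(x, 2 * x[n] - x[n - seq_len(m - n)])
  } else {
    m <- n
    xp <- x
  }
  X <- stats::fft(xp)
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((m + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / m
  z[seq_len(n)]
}

# Welch-averaged power spectral density of one vector.
# win_sec window length, step = win_sec - overlap_sec (spectrogram convention).
welch_psd_vec <- function(x, fs, win_sec = 4, overlap_sec = 1) {
  nper <- round(win_sec * fs)
  if (length(x) < nper) stop("segment shorter than one PSD window")
  step <- nper - round(overlap_sec * fs)
  stopifnot(step >= 1)
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nper %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / scale
    p <- P[seq_len(nf)]
    if (nper %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1) * fs / nper, power = acc / length(starts))
}
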