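# Independent oracles used across tests. These are deliberately naive
# implementations (per-sample scans, dense grids, textbook samplers) kept
# separate from the package's own code paths.

# Brute-force per-sample burst scan: walk the envelope sample by sample,
# opening a span when it rises above thresh, closing when it falls back,
# and keeping spans by the duration and max rules.
naive_burst_scan <- function(envelope, thresh, thresh2, fs, min_dur = 0.1) {
  spans <- list()
  open <- FALSE
  for (i in seq_along(envelope)) {
    above <- !is.na(envelope[i]) && envelope[i] > thresh
    if (above && !open) {
      open <- TRUE; s <- i
    }
    if (!above && open) {
      open <- FALSE
      spans[[length(spans) + 1]] <- c(s, i)
    }
  }
  if (open) spans[[length(spans) + 1]] <- c(s, length(envelope) + 1)
  keep <- Filter(function(sp) {
    (sp[2] - sp[1]) / fs >= min_dur &&
      max(envelope[sp[1]:(sp[2] - 1)]) > thresh2
  }, spans)
  if (!length(keep))
    return(data.frame(start_sample = integer(0), end_sample = integer(0)))
  m <- do.call(rbind, keep)
  data.frame(start_sample = m[, 1], end_sample = m[, 2])
}

# von Mises sampler (Best & Fisher 1979 rejection), vectorized
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, theta)
  }
  wrap <- (out[seq_len(n)] + mu + pi) %% (2 * pi) - pi
  wrap
}

# overlap of [a1,a2) and [b1,b2)
interval_overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))
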