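# Local/global classification of cortical burst timepoints: channel-fraction
# series, two-component Gaussian mixture threshold on the pooled per-day
# fraction distribution, 0/1/2 labeling, population-event segmentation, and
# subcortical co-occurrence.

#' Fraction of cortical channels bursting per sample
#'
#' Excluded channels are removed from both numerator and denominator.
#'
#' @param masks Logical samples-by-channels burst mask matrix.
#' @param exclude_channels Channels to drop.
#' @return List: `fraction` (0..1 per sample), `count` (bursting channels per
#'   sample), `n_included`.
#' @export
fraction_bursting <- function(masks, exclude_channels = integer(0)) {
  keep <- setdiff(seq_len(ncol(masks)), exclude_channels)
  if (!length(keep)) stop("no included channels")
  count <- rowSums(masks[, keep, drop = FALSE])
  list(fraction = count / length(keep), count = count,
       n_included = length(keep))
}

# Weighted 1-D EM for a 2-component Gaussian mixture.
# w: per-sample weights (per-day equal weighting upstream).
gmm2_em <- function(x, w = NULL, n_restarts = 10, tol = 1e-6,
                    max_iter = 500, seed = 0L) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  qs <- stats::quantile(x, c(0.25, 0.75))
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1) as.numeric(qs) else sort(sample(x, 2))
    sig <- rep(max(stats::sd(x), 1e-3), 2)
    pi_k <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- pi_k[1] * stats::dnorm(x, mu[1], sig[1])
      d2 <- pi_k[2] * stats::dnorm(x, mu[2], sig[2])
      tot <- d1 + d2
      tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
      g1 <- d1 / tot
      ll <- sum(w * log(tot))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
      w1 <- sum(w * g1); w2 <- sum(w * (1 - g1))
      pi_k <- c(w1, w2)
      mu <- c(sum(w * g1 * x) / w1, sum(w * (1 - g1) * x) / w2)
      sig <- sqrt(c(sum(w * g1 * (x - mu[1])^2) / w1,
                    sum(w * (1 - g1) * (x - mu[2])^2) / w2))
      sig <- pmax(sig, 1e-4)
    }
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, weights = pi_k, means = mu, sds = sig)
  }
  ord <- order(best$means)
  list(weights = best$weights[ord], means = best$means[ord],
       sds = best$sds[ord], loglik = best$ll)
}

#' Crossing point of two weighted Gaussian densities
#'
#' Root of `w1 * N(x; m1, s1) = w2 * N(x; m2, s2)` strictly between the two
#' means, solved in closed form (quadratic in x) with a dense-grid fallback.
#'
#' @param weights,means,sds Length-2 component parameters (means ascending).
#' @return The crossing abscissa.
#' @export
gaussian_crossing <- function(weights, means, sds) {
  stopifnot(length(means) == 2, means[1] < means[2])
  a <- 1 / (2 * sds[2]^2) - 1 / (2 * sds[1]^2)
  b <- means[1] / sds[1]^2 - means[2] / sds[2]^2
  cc <- means[2]^2 / (2 * sds[2]^2) - means[1]^2 / (2 * sds[1]^2) +
    log((weights[1] * sds[2]) / (weights[2] * sds[1]))
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-15) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > means[1] & roots < means[2]]
  if (length(inside) == 1) return(inside)
  # fallback: dense grid between the means
  grid <- seq(means[1], means[2], length.out = 20001)
  diff <- abs(weights[1] * stats::dnorm(grid, means[1], sds[1]) -
                weights[2] * stats::dnorm(grid, means[2], sds[2]))
  grid[which.min(diff)]
}

#' Fit the local/global channel-fraction threshold
#'
#' Pools per-day fraction samples (restricted upstream to cortical-burst
#' timepoints, i.e. count >= 3), reweights each day's samples to equal total
#' weight (the tractable equivalent of averaging the per-day distributions),
#' fits a two-component Gaussian mixture by EM (10 restarts, tol 1e-6,
#' fixed internal seed), and returns the density crossing between the two
#' component means as the threshold used for all days.
#'
#' @param fractions_by_day List of numeric vectors, one per day, of channel
#'   fractions at cortical-burst timepoints.
#' @return Object of class `local_global_threshold`: `threshold`, `weights`,
#'   `means`, `sds`, `n_days`, `collapsed` (TRUE if the mixture degenerated
#'   and the midpoint fallback was used).
#' @export
fit_local_global_threshold <- function(fractions_by_day) {
  if (!is.list(fractions_by_day)) fractions_by_day <- list(fractions_by_day)
  fractions_by_day <- Filter(length, fractions_by_day)
  if (!length(fractions_by_day)) stop("no fraction samples supplied")
  if (length(fractions_by_day) < 2)
    warning("fitting local/global threshold on a single day")
  x <- unlist(fractions_by_day, use.names = FALSE)
  w <- unlist(lapply(fractions_by_day, function(v) rep(1 / length(v),
                                                       length(v))))
  fit <- gmm2_em(x, w)
  collapsed <- abs(diff(fit$means)) < sum(fit$sds) / 10
  threshold <- if (collapsed) {
    warning("mixture components collapsed; using midpoint fallback")
    mean(fit$means)
  } else gaussian_crossing(fit$weights, fit$means, fit$sds)
  structure(list(threshold = threshold, weights = fit$weights,
                 means = fit$means, sds = fit$sds,
                 n_days = length(fractions_by_day), collapsed = collapsed),
            class = "local_global_threshold")
}

#' Label timepoints 0/1/2 and segment population burst events
#'
#' Label 2 (global) iff `fraction > threshold`; label 1 (local) iff
#' `fraction <= threshold` and at least `min_channels` channels are
#' bursting; else 0. Population events are maximal constant-label runs of
#' 1s or 2s lasting at least `min_dur` seconds; a direct local-to-global
#' transition breaks both runs. Per event, `fracact` is the fraction of the
#' event's samples during which each channel is itself bursting.
#'
#' @param frac Output of [fraction_bursting()].
#' @param threshold Scalar threshold or a `local_global_threshold`.
#' @param masks The samples-by-channels mask matrix (for fracact).
#' @param fs Sampling rate, Hz.
#' @param min_channels Minimum bursting-channel count for a cortical burst
#'   timepoint (absolute, default 3).
#' @param min_dur Minimum event duration, s.
#' @return List: `labels` (integer per sample), `events`
#'   data.frame(category, start_sample, end_sample, start_s, end_s,
#'   duration_s), `fracact` (events x channels matrix).
#' @export
label_and_segment <- function(frac, threshold, masks, fs, min_channels = 3,
                              min_dur = 0.100) {
  if (inherits(threshold, "local_global_threshold"))
    threshold <- threshold$threshold
  stopifnot(threshold > 0, threshold < 1)
  labels <- integer(length(frac$fraction))
  labels[frac$fraction > threshold] <- 2L
  labels[frac$fraction <= threshold & frac$count >= min_channels] <- 1L
  r <- rle(labels)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values > 0 & r$lengths / fs >= min_dur
  events <- data.frame(
    category = c("none", "local", "global")[r$values[keep] + 1L],
    start_sample = starts[keep], end_sample = ends[keep] + 1L)
  events$start_s <- (events$start_sample - 1) / fs
  events$end_s <- (events$end_sample - 1) / fs
  events$duration_s <- events$end_s - events$start_s
  fracact <- matrix(0, nrow(events), ncol(masks))
  for (i in seq_len(nrow(events))) {
    idx <- events$start_sample[i]:(events$end_sample[i] - 1)
    fracact[i, ] <- colMeans(masks[idx, , drop = FALSE])
  }
  rownames(events) <- NULL
  list(labels = labels, events = events, fracact = fracact)
}

#' Assign channel burst events to population categories
#'
#' Each per-channel burst is tagged with the category (`local`, `global` or
#' `none`) of the population event containing its midpoint, enabling
#' feature contrasts (amplitude, duration, frequency) between event
#' classes.
#'
#' @param channel_events Per-channel burst table (`start_s`, `end_s`).
#' @param pop_events Population event table from [label_and_segment()].
#' @return `channel_events` with a `category` column added.
#' @export
assign_burst_category <- function(channel_events, pop_events) {
  mid <- (channel_events$start_s + channel_events$end_s) / 2
  cat <- rep("none", length(mid))
  for (i in seq_len(nrow(pop_events))) {
    hit <- mid >= pop_events$start_s[i] & mid < pop_events$end_s[i]
    cat[hit] <- pop_events$category[i]
  }
  channel_events$category <- cat
  channel_events
}

#' Subcortical co-occurrence of cortical burst events
#'
#' For each population-event category, the fraction of in-event samples at
#' which at least one subcortical channel is inside a subcortical burst.
#'
#' @param events Population event table from [label_and_segment()].
#' @param sub_masks Logical samples-by-channels subcortical burst masks on
#'   the same sample grid.
#' @return `data.frame(category, fraction, n_samples)`.
#' @export
subcortical_cooccurrence <- function(events, sub_masks) {
  if (!ncol(sub_masks)) stop("no subcortical channels")
  any_sub <- rowSums(sub_masks) > 0
  cats <- c("local", "global")
  res <- lapply(cats, function(cat) {
    ev <- events[events$category == cat, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(ev)), function(i)
      ev$start_sample[i]:(ev$end_sample[i] - 1)))
    data.frame(category = cat,
               fraction = if (length(idx)) mean(any_sub[idx]) else NA_real_,
               n_samples = length(idx))
  })
  do.call(rbind, res)
}
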