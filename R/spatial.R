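# Spatial clustering of burst activity on the electrode grid: activity-
# weighted burst centers, weighted mean distance to center, and a
# column-shuffle permutation null that preserves the average number of
# channels active per burst and each channel's total activation.

#' Activity-weighted burst center and mean distance to center
#'
#' `loccenter = sum(fracact_c * loc_c) / sum(fracact_c)` and
#' `distcenter = sum(fracact_c * ||loc_c - loccenter||) / sum(fracact_c)`
#' (Euclidean norm), where `fracact_c` is the fraction of the event's
#' duration channel `c` is bursting.
#'
#' @param fracact Per-channel activity fractions for one event.
#' @param geometry `data.frame(channel, x_mm, y_mm)` aligned with
#'   `fracact`.
#' @return `list(loccenter = c(x, y), distcenter)` in mm.
#' @export
burst_center_and_distance <- function(fracact, geometry) {
  stopifnot(length(fracact) == nrow(geometry))
  w <- sum(fracact)
  if (w <= 0) stop("all fracact are zero")
  cx <- sum(fracact * geometry$x_mm) / w
  cy <- sum(fracact * geometry$y_mm) / w
  d <- sqrt((geometry$x_mm - cx)^2 + (geometry$y_mm - cy)^2)
  list(loccenter = c(x = cx, y = cy), distcenter = sum(fracact * d) / w)
}

# concatenate per-event binary channels-x-time arrays along time
concat_event_arrays <- function(event_masks) {
  stopifnot(length(event_masks) >= 1)
  nch <- nrow(event_masks[[1]])
  stopifnot(all(vapply(event_masks, nrow, 0L) == nch))
  do.call(cbind, event_masks)
}

#' Column-shuffle null distribution of burst-center distances
#'
#' All events' binary channels-by-time arrays are concatenated along time;
#' each shuffle permutes whole columns (the full channel vector at one
#' sample), re-cuts the array at the original event lengths in their
#' original order, and recomputes the weighted center distance per
#' re-segmented event. The column multiset is conserved exactly, hence so
#' are the average number of active channels per burst and the per-channel
#' activation totals.
#'
#' @param event_masks List of logical channels-by-time matrices, one per
#'   event (same channel axis).
#' @param geometry Channel geometry, rows aligned with the channel axis.
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed RNG seed for the permutations.
#' @param keep_first If TRUE, attach the first permuted array as attribute
#'   `first_shuffle` (used to assert conservation properties).
#' @return List: `null_dist` (length `n_events * n_shuffles`),
#'   `shuffle_mean`, `n_events`.
#' @export
shuffle_null_distances <- function(event_masks, geometry, n_shuffles = 100,
                                   seed = 1L, keep_first = FALSE) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  big <- concat_event_arrays(event_masks)
  lens <- vapply(event_masks, ncol, 0L)
  set.seed(seed)
  out <- numeric(0)
  first <- NULL
  for (s in seq_len(n_shuffles)) {
    perm <- big[, sample.int(ncol(big)), drop = FALSE]
    if (s == 1 && keep_first) first <- perm
    stop_at <- cumsum(lens)
    start_at <- stop_at - lens + 1L
    d <- vapply(seq_along(lens), function(i) {
      fr <- rowMeans(perm[, start_at[i]:stop_at[i], drop = FALSE])
      if (sum(fr) <= 0) return(NA_real_)
      burst_center_and_distance(fr, geometry)$distcenter
    }, 0)
    out <- c(out, d)
  }
  res <- list(null_dist = out, shuffle_mean = mean(out, na.rm = TRUE),
              n_events = length(lens))
  if (keep_first) attr(res, "first_shuffle") <- first
  res
}

#' Shuffle-centered clustering statistic
#'
#' Centers each event's true distance by the shuffle mean
#' (`centered = distcenter - shuffle_mean`); negative values mean the burst
#' is more spatially clustered than the time-shuffled null.
#'
#' @param true_dist True per-event `distcenter` values, mm.
#' @param null Output of [shuffle_null_distances()] for the same session
#'   and epoch class.
#' @return List: `centered` per event, `mean`, `se`, `frac_negative`.
#' @export
clustering_statistic <- function(true_dist, null) {
  centered <- true_dist - null$shuffle_mean
  n <- sum(!is.na(centered))
  list(centered = centered, mean = mean(centered, na.rm = TRUE),
       se = stats::sd(centered, na.rm = TRUE) / sqrt(max(n, 1)),
       frac_negative = mean(centered < 0, na.rm = TRUE))
}

#' Event masks and spatial summary for population events
#'
#' Convenience: slices per-event channels-by-time binary arrays out of the
#' session mask matrix, computes true center/distance per event from
#' `fracact`, the shuffle null, and the centered statistic.
#'
#' @param events Population event table (one category).
#' @param fracact Matching events-by-channels fracact matrix.
#' @param masks Samples-by-channels logical burst masks.
#' @param geometry Channel geometry.
#' @param n_shuffles,seed Passed to [shuffle_null_distances()].
#' @return `data.frame(event, x_mm, y_mm, distcenter_mm, centered_mm)` plus
#'   attributes `shuffle_mean`, `summary`.
#' @export
spatial_summary <- function(events, fracact, masks, geometry,
                            n_shuffles = 100, seed = 1L) {
  stopifnot(nrow(events) == nrow(fracact))
  if (!nrow(events))
    return(data.frame(event = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), distcenter_mm = numeric(0),
                      centered_mm = numeric(0)))
  cen <- t(vapply(seq_len(nrow(events)), function(i) {
    b <- burst_center_and_distance(fracact[i, ], geometry)
    c(b$loccenter, d = b$distcenter)
  }, c(x = 0, y = 0, d = 0)))
  event_masks <- lapply(seq_len(nrow(events)), function(i)
    t(masks[events$start_sample[i]:(events$end_sample[i] - 1), ,
            drop = FALSE]))
  null <- shuffle_null_distances(event_masks, geometry, n_shuffles, seed)
  stat <- clustering_statistic(cen[, "d"], null)
  out <- data.frame(event = seq_len(nrow(events)), x_mm = cen[, "x"],
                    y_mm = cen[, "y"], distcenter_mm = cen[, "d"],
                    centered_mm = stat$centered)
  attr(out, "shuffle_mean") <- null$shuffle_mean
  attr(out, "summary") <- stat[c("mean", "se", "frac_negative")]
  out
}
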