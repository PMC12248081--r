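# Session bundle container I/O: HDF5 for the heavyweight arrays
# (/lfp/cortex, /lfp/subcortex, /spikes/<unit>, /kinematics, /geometry)
# and TSV for event/ground-truth tables.

#' Write a session bundle to HDF5
#'
#' @param bundle A `session_bundle`.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_session_bundle <- function(bundle, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h))
  rhdf5::h5createGroup(h, "lfp")
  rhdf5::h5write(bundle$lfp_cortex, h, "lfp/cortex")
  rhdf5::h5write(bundle$lfp_subcortex, h, "lfp/subcortex")
  rhdf5::h5createGroup(h, "spikes")
  for (u in names(bundle$spikes))
    rhdf5::h5write(bundle$spikes[[u]], h, paste0("spikes/", u))
  rhdf5::h5createGroup(h, "waveforms")
  rhdf5::h5write(bundle$waveforms$mean, h, "waveforms/mean")
  rhdf5::h5write(bundle$waveforms$sd, h, "waveforms/sd")
  rhdf5::h5write(bundle$geometry, h, "geometry")
  rhdf5::h5write(bundle$kinematics, h, "kinematics")
  trials <- bundle$trials
  trials$rewarded <- as.integer(trials$rewarded)  # rhdf5 drops logicals
  rhdf5::h5write(trials, h, "trials")
  rhdf5::h5write(bundle$prestroke, h, "prestroke")
  meta <- data.frame(session_id = bundle$session_id, fs_raw = bundle$fs_raw,
                     frame_rate = bundle$frame_rate,
                     beta_low = bundle$beta_band[1],
                     beta_high = bundle$beta_band[2],
                     crossing_offset = bundle$crossing_offset)
  rhdf5::h5write(meta, h, "meta")
  invisible(path)
}

#' Read a session bundle from HDF5
#'
#' @param path `.h5` file written by [write_session_bundle()].
#' @return A `session_bundle`.
#' @export
read_session_bundle <- function(path) {
  undim <- function(df) {        # rhdf5 returns 1-d arrays for columns
    for (j in seq_along(df)) df[[j]] <- as.vector(df[[j]])
    df
  }
  meta <- rhdf5::h5read(path, "meta")
  unit_names <- rhdf5::h5ls(path)
  unit_names <- unit_names$name[unit_names$group == "/spikes"]
  spikes <- lapply(unit_names, function(u)
    as.numeric(rhdf5::h5read(path, paste0("spikes/", u))))
  names(spikes) <- unit_names
  spikes <- spikes[order(as.integer(sub("unit", "", unit_names)))]
  trials <- undim(rhdf5::h5read(path, "trials"))
  trials$rewarded <- as.logical(trials$rewarded)
  structure(list(
    session_id = as.character(meta$session_id),
    lfp_cortex = rhdf5::h5read(path, "lfp/cortex"),
    lfp_subcortex = rhdf5::h5read(path, "lfp/subcortex"),
    fs_raw = as.numeric(meta$fs_raw),
    geometry = undim(rhdf5::h5read(path, "geometry")),
    spikes = spikes,
    waveforms = list(mean = rhdf5::h5read(path, "waveforms/mean"),
                     sd = rhdf5::h5read(path, "waveforms/sd")),
    trials = trials,
    kinematics = undim(rhdf5::h5read(path, "kinematics")),
    crossing_offset = as.numeric(meta$crossing_offset),
    frame_rate = as.numeric(meta$frame_rate),
    beta_band = c(as.numeric(meta$beta_low), as.numeric(meta$beta_high)),
    prestroke = undim(rhdf5::h5read(path, "prestroke"))),
    class = "session_bundle")
}

#' Write a table as TSV
#'
#' @param x data.frame (list columns are collapsed to comma strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  for (j in seq_along(x))
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), "")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground truth tables as TSV
#'
#' @param truth A `session_truth`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$burst_events, file.path(dir, "burst_events.tsv"))
  write_tsv(truth$spike_coupling, file.path(dir, "spike_coupling.tsv"))
  write_tsv(truth$trial_events, file.path(dir, "trial_events.tsv"))
  write_tsv(truth$slowdown_intervals, file.path(dir, "slowdowns.tsv"))
  invisible(dir)
}
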