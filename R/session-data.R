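#' Trial-structured recording session
#'
#' A `session_data` object holds one recording session in the trial-resolved
#' form all analyses in this package operate on: a trial x unit matrix of
#' spike counts in the stimulus window, per-trial grating condition labels,
#' per-trial mean treadmill speed, and optional eye signals (saccade events
#' and pupil size). Units recorded in only part of the session are supported
#' by `NA` entries in `counts` (a float view; non-missing entries are
#' integer-valued).
#'
#' Condition labels are stored as 1-based indices: `orientation` into the 12
#' orientations 0..330 degrees in 30 degree steps, `spatial_freq` into
#' \{1, 2, 4\} cyc/deg, `drift_speed` into \{1, 2\} deg/s. All times are in
#' seconds, speeds in cm/s, angles in degrees for both species.
#'
#' @param session_id Character identifier.
#' @param species One of `"mouse"`, `"marmoset"`, `"synthetic"`.
#' @param counts Trial x unit numeric matrix of non-negative integer-valued
#'   spike counts; `NA` marks trials on which a unit was not recorded.
#' @param duration Per-trial stimulus-window length, s.
#' @param orientation,spatial_freq,drift_speed Per-trial 1-based condition
#'   indices (`<= 12`, `<= 3`, `<= 2`).
#' @param running_speed Per-trial mean treadmill speed, cm/s.
#' @param trial_onsets,trial_offsets Stimulus on/off times, s from session
#'   start; onsets strictly increasing, offsets > onsets.
#' @param running_trace Optional list with `time` and `speed` vectors (finely
#'   sampled treadmill speed).
#' @param saccade_times,saccade_magnitudes Optional saccade event times (s)
#'   and vector magnitudes (deg).
#' @param pupil Optional per-trial pupil size, arbitrary units.
#' @return An object of class `session_data`.
#' @seealso [read_session()], [write_session()], [generate_session()]
#' @export
session_data <- function(session_id, species, counts, duration,
                         orientation, spatial_freq, drift_speed,
                         running_speed, trial_onsets, trial_offsets,
                         running_trace = NULL, saccade_times = NULL,
                         saccade_magnitudes = NULL, pupil = NULL) {
  s <- structure(list(
    session_id = as.character(session_id),
    species = match.arg(species, c("mouse", "marmoset", "synthetic")),
    counts = {cm <- as.matrix(counts); storage.mode(cm) <- "double"; cm},
    duration = as.numeric(duration),
    orientation = as.integer(orientation),
    spatial_freq = as.integer(spatial_freq),
    drift_speed = as.integer(drift_speed),
    running_speed = as.numeric(running_speed),
    trial_onsets = as.numeric(trial_onsets),
    trial_offsets = as.numeric(trial_offsets),
    running_trace = running_trace,
    saccade_times = if (is.null(saccade_times)) NULL else as.numeric(saccade_times),
    saccade_magnitudes = if (is.null(saccade_magnitudes)) NULL else as.numeric(saccade_magnitudes),
    pupil = if (is.null(pupil)) NULL else as.numeric(pupil)
  ), class = "session_data")
  validate_session(s)
  s
}

#' Validate a session against its structural invariants
#'
#' Checks non-negative integer-valued counts, consistent per-trial vector
#' lengths, in-range condition indices, and strictly increasing trial onsets
#' with offsets after onsets.
#'
#' @param session A `session_data` object.
#' @return The session, invisibly; signals a validation error otherwise.
#' @export
validate_session <- function(session) {
  s <- session
  n_trials <- nrow(s$counts)
  per_trial <- list(duration = s$duration, orientation = s$orientation,
                    spatial_freq = s$spatial_freq, drift_speed = s$drift_speed,
                    running_speed = s$running_speed,
                    trial_onsets = s$trial_onsets, trial_offsets = s$trial_offsets)
  for (nm in names(per_trial)) {
    if (length(per_trial[[nm]]) != n_trials)
      stop("validation error: length of '", nm, "' (", length(per_trial[[nm]]),
           ") does not match number of trials (", n_trials, ")")
  }
  cnt <- s$counts[!is.na(s$counts)]
  if (any(cnt < 0)) stop("validation error: negative spike counts")
  if (any(abs(cnt - round(cnt)) > 1e-9)) stop("validation error: non-integer spike counts")
  if (any(s$orientation < 1L | s$orientation > 12L))
    stop("validation error: orientation index outside 1..12")
  if (any(s$spatial_freq < 1L | s$spatial_freq > 3L))
    stop("validation error: spatial_freq index outside 1..3")
  if (any(s$drift_speed < 1L | s$drift_speed > 2L))
    stop("validation error: drift_speed index outside 1..2")
  if (any(diff(s$trial_onsets) <= 0))
    stop("validation error: trial_onsets not strictly increasing")
  if (any(s$trial_offsets <= s$trial_onsets))
    stop("validation error: trial_offsets not greater than trial_onsets")
  if (!is.null(s$pupil) && length(s$pupil) != n_trials)
    stop("validation error: pupil length does not match number of trials")
  if (!is.null(s$saccade_times) &&
      length(s$saccade_times) != length(s$saccade_magnitudes))
    stop("validation error: saccade_times and saccade_magnitudes differ in length")
  invisible(session)
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("<session_data> %s (%s): %d trials x %d units\n",
              x$session_id, x$species, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  running on %.1f%% of trials (speed >= 3 cm/s); eye data: %s\n",
              100 * mean(x$running_speed >= 3),
              if (is.null(x$saccade_times)) "absent" else "present"))
  invisible(x)
}

#' Number of trials / units in a session
#' @param session A `session_data` object.
#' @return Integer count.
#' @export
n_trials <- function(session) nrow(session$counts)

#' @rdname n_trials
#' @export
n_units <- function(session) ncol(session$counts)

# ---- HDF5 serialization ----------------------------------------------------

#' Write a session to an HDF5 file
#'
#' One file per session: group `/meta` carries `session_id` and `species` as
#' attributes; `/trials` holds the per-trial datasets (`counts` as a float
#' matrix with NaN for missing unit-trials); `/eye` (saccade events, pupil)
#' and `/trace` (finely sampled running speed) are written only when present.
#'
#' @param session A `session_data` object.
#' @param path Output file path; overwritten if it exists.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "trials")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  rhdf5::h5writeAttribute(session$session_id, gid, "session_id")
  rhdf5::h5writeAttribute(session$species, gid, "species")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  cnt <- session$counts
  storage.mode(cnt) <- "double"
  cnt[is.na(cnt)] <- NaN
  rhdf5::h5write(cnt, path, "trials/counts")
  for (nm in c("duration", "orientation", "spatial_freq", "drift_speed",
               "running_speed")) {
    rhdf5::h5write(session[[nm]], path, paste0("trials/", nm))
  }
  rhdf5::h5write(session$trial_onsets, path, "trials/onsets")
  rhdf5::h5write(session$trial_offsets, path, "trials/offsets")
  if (!is.null(session$saccade_times) || !is.null(session$pupil)) {
    rhdf5::h5createGroup(path, "eye")
    if (!is.null(session$saccade_times)) {
      rhdf5::h5write(session$saccade_times, path, "eye/saccade_times")
      rhdf5::h5write(session$saccade_magnitudes, path, "eye/saccade_magnitudes")
    }
    if (!is.null(session$pupil)) rhdf5::h5write(session$pupil, path, "eye/pupil")
  }
  if (!is.null(session$running_trace)) {
    rhdf5::h5createGroup(path, "trace")
    rhdf5::h5write(session$running_trace$time, path, "trace/time")
    rhdf5::h5write(session$running_trace$speed, path, "trace/speed")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a session from an HDF5 file
#'
#' Inverse of [write_session()]; the returned object passes
#' [validate_session()] and round-trips counts bit-exactly.
#'
#' @param path Path to a session HDF5 file.
#' @return A `session_data` object.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("schema error: file not found: ", path)
  contents <- rhdf5::h5ls(path)
  present <- file.path(contents$group, contents$name)
  present <- sub("^//", "/", present)
  required <- c("/trials/counts", "/trials/duration", "/trials/orientation",
                "/trials/spatial_freq", "/trials/drift_speed",
                "/trials/running_speed", "/trials/onsets", "/trials/offsets")
  missing <- setdiff(required, present)
  if (length(missing) > 0)
    stop("schema error: missing dataset(s): ", paste(missing, collapse = ", "))
  rd <- function(nm) rhdf5::h5read(path, nm)
  cnt <- rd("trials/counts")
  cnt[is.nan(cnt)] <- NA_real_
  meta <- rhdf5::h5readAttributes(path, "meta")
  session_id <- meta$session_id
  species <- meta$species
  trace <- if ("/trace/speed" %in% present)
    list(time = as.numeric(rd("trace/time")), speed = as.numeric(rd("trace/speed")))
  s <- session_data(
    session_id = session_id, species = species, counts = cnt,
    duration = rd("trials/duration"),
    orientation = rd("trials/orientation"),
    spatial_freq = rd("trials/spatial_freq"),
    drift_speed = rd("trials/drift_speed"),
    running_speed = rd("trials/running_speed"),
    trial_onsets = rd("trials/onsets"),
    trial_offsets = rd("trials/offsets"),
    running_trace = trace,
    saccade_times = if ("/eye/saccade_times" %in% present) rd("eye/saccade_times"),
    saccade_magnitudes = if ("/eye/saccade_magnitudes" %in% present) rd("eye/saccade_magnitudes"),
    pupil = if ("/eye/pupil" %in% present) rd("eye/pupil")
  )
  rhdf5::h5closeAll()
  s
}

# ---- Inclusion filters -----------------------------------------------------

#' Session inclusion filter
#'
#' A session enters the population analyses only if it has more than 250
#' trials and the proportion of (unambiguously labelled) trials spent running
#' is between 10% and 90% inclusive — sessions in which the animal nearly
#' always or nearly never ran carry no information about running modulation.
#'
#' @param sessions List of `session_data` objects.
#' @param labels List of [split_by_running()] results, one per session.
#' @return A `filter_report` data frame with columns `id`, `included`,
#'   `reason` (non-empty exactly for exclusions).
#' @export
filter_sessions <- function(sessions, labels) {
  if (length(sessions) == 0) stop("empty session list")
  stopifnot(length(sessions) == length(labels))
  rows <- lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    lab <- labels[[k]]$label
    nt <- n_trials(s)
    n_run <- sum(lab == "running")
    n_stat <- sum(lab == "stationary")
    if (nt <= 250)
      return(data.frame(id = s$session_id, included = FALSE,
                        reason = sprintf("only %d trials (need > 250)", nt)))
    if (n_run + n_stat == 0)
      return(data.frame(id = s$session_id, included = FALSE,
                        reason = "no unambiguous running/stationary trials"))
    prop <- n_run / (n_run + n_stat)
    if (prop < 0.10 || prop > 0.90)
      return(data.frame(id = s$session_id, included = FALSE,
                        reason = sprintf("running proportion %.3f outside [0.10, 0.90]", prop)))
    data.frame(id = s$session_id, included = TRUE, reason = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("filter_report", class(out))
  out
}

#' Unit inclusion filter
#'
#' A unit is retained when it was recorded on more than 300 trials and its
#' mean firing rate (total spikes over total stimulus time on its recorded
#' trials) exceeds 1 spike/s.
#'
#' @param session A `session_data` object.
#' @return A `filter_report` data frame with one row per unit (`id` is the
#'   column index).
#' @export
filter_units <- function(session) {
  cnt <- session$counts
  dur <- session$duration
  rows <- lapply(seq_len(ncol(cnt)), function(i) {
    ok <- !is.na(cnt[, i])
    ntr <- sum(ok)
    rate <- if (ntr > 0) sum(cnt[ok, i]) / sum(dur[ok]) else 0
    if (ntr <= 300)
      data.frame(id = i, included = FALSE,
                 reason = sprintf("only %d trials (need > 300)", ntr))
    else if (rate <= 1)
      data.frame(id = i, included = FALSE,
                 reason = sprintf("mean rate %.3f Hz (need > 1)", rate))
    else data.frame(id = i, included = TRUE, reason = "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("filter_report", class(out))
  out
}
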