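#' Spike-count analysis window for one stimulus presentation
#'
#' Responses are counted from 50 ms after grating onset to 50 ms after
#' grating offset, absorbing response latency while keeping the window length
#' equal to the presentation length.
#'
#' @param onset,offset Stimulus on/off times, s.
#' @return Numeric vector `c(start, end)` in seconds.
#' @export
spike_count_window <- function(onset, offset) {
  c(onset + 0.05, offset + 0.05)
}

#' Per-trial firing rates
#'
#' Converts the stored windowed spike counts to rates in Hz by dividing by
#' the per-trial window length.
#'
#' @param session A `session_data` object.
#' @return Trial x unit numeric matrix of rates (Hz); `NA` where the unit was
#'   not recorded.
#' @export
trial_rates <- function(session) {
  if (any(session$duration <= 0)) stop("non-positive trial duration")
  session$counts / session$duration
}

orientation_deg <- (0:11) * 30

#' Orientation tuning curves with spatial-frequency weighting
#'
#' For each unit, mean rates are computed in the 12 x 3 orientation x
#' spatial-frequency grid (drift speeds pooled). Because running behaviour —
#' not the experimenter — determines how trials fall across conditions, the
#' orientation curve is a weighted average across spatial frequencies, with
#' weights proportional to the unit's mean response at each spatial frequency
#' (clipped at zero, normalized to sum 1). Cells of the grid with no trials
#' are excluded from the weighting rather than imputed.
#'
#' @param rates Trial x unit rate matrix from [trial_rates()].
#' @param session The `session_data` the rates came from.
#' @return A list of `tuning_curve` objects, one per unit, each with fields
#'   `unit_id`, `mean_rate` (12 x 3, Hz), `sf_weights`, `orientation_curve`
#'   (12, Hz), `baseline` (its minimum, Hz), `osi`, `preferred_orientation`
#'   (deg), `tuned`.
#' @export
compute_tuning <- function(rates, session) {
  stopifnot(nrow(rates) == n_trials(session))
  lapply(seq_len(ncol(rates)), function(i) {
    r <- rates[, i]
    ok <- !is.na(r)
    if (!any(ok)) stop("unit ", i, " has no trials")
    mean_rate <- matrix(NA_real_, 12, 3,
                        dimnames = list(orientation = orientation_deg,
                                        sf = c(1, 2, 4)))
    for (f in 1:3) for (o in 1:12) {
      sel <- ok & session$orientation == o & session$spatial_freq == f
      if (any(sel)) mean_rate[o, f] <- mean(r[sel])
    }
    sf_mean <- colMeans(mean_rate, na.rm = TRUE)
    sf_w <- pmax(sf_mean, 0)
    sf_w <- if (sum(sf_w) > 0) sf_w / sum(sf_w) else rep(1 / 3, 3)
    curve <- vapply(1:12, function(o) {
      avail <- !is.na(mean_rate[o, ])
      if (!any(avail)) return(NA_real_)
      w <- sf_w[avail]
      if (sum(w) == 0) return(mean(mean_rate[o, avail]))
      sum(mean_rate[o, avail] * w) / sum(w)
    }, numeric(1))
    tc <- structure(list(unit_id = i, mean_rate = mean_rate, sf_weights = sf_w,
                         orientation_curve = curve,
                         baseline = min(curve, na.rm = TRUE),
                         preferred_orientation =
                           orientation_deg[which.max(curve)]),
                    class = "tuning_curve")
    tc$osi <- osi(tc)
    tc$tuned <- is_tuned(tc)
    tc
  })
}

#' Orientation selectivity index
#'
#' Vector-sum selectivity on the doubled angle: with `r` the
#' baseline-subtracted orientation curve (baseline = curve minimum, so `r >=
#' 0`) and theta the orientation,
#' `OSI = sqrt((sum(r sin 2theta))^2 + (sum(r cos 2theta))^2) / sum(r)`.
#' A flat curve gives 0; a curve responding at a single orientation gives 1.
#' Returns 0 when `sum(r) = 0`.
#'
#' @param curve A `tuning_curve` object, or a numeric vector of 12 rates at
#'   orientations 0, 30, ..., 330 degrees.
#' @return OSI in `[0, 1]`.
#' @export
osi <- function(curve) {
  oc <- if (inherits(curve, "tuning_curve")) curve$orientation_curve else curve
  stopifnot(length(oc) == 12)
  keep <- !is.na(oc)
  th <- (orientation_deg * pi / 180)[keep]
  oc <- oc[keep]
  r <- oc - min(oc)
  if (any(r < 0)) stop("internal error: negative baseline-subtracted rate")
  if (sum(r) == 0) return(0)
  sqrt(sum(r * sin(2 * th))^2 + sum(r * cos(2 * th))^2) / sum(r)
}

#' Is a unit orientation-tuned?
#'
#' A unit counts as tuned when its OSI strictly exceeds 0.2.
#'
#' @param curve A `tuning_curve` object or a numeric OSI value.
#' @return Logical.
#' @export
is_tuned <- function(curve) {
  val <- if (inherits(curve, "tuning_curve")) curve$osi else curve
  val > 0.2
}

#' Tuning summary table
#'
#' @param curves List of `tuning_curve` objects from [compute_tuning()].
#' @return Data frame with `unit_id`, `preferred_orientation`, `osi`, `tuned`.
#' @export
tuning_table <- function(curves) {
  do.call(rbind, lapply(curves, function(tc)
    data.frame(unit_id = tc$unit_id,
               preferred_orientation = tc$preferred_orientation,
               osi = tc$osi, tuned = tc$tuned)))
}
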