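#' Per-trial eye-movement features
#'
#' Counts saccades whose time falls in the analysis bin of each stimulus
#' presentation — from 0.2 s before onset to 0.1 s after offset — and
#' averages the magnitudes of the counted saccades (NaN when none occur).
#' Pupil size is expressed as a percentage of the stationary-trial mean
#' (100% = stationary average).
#'
#' @param session A `session_data` object with saccade events (and
#'   optionally pupil).
#' @param labels [split_by_running()] output, used to normalize pupil to the
#'   stationary mean; defaults to labelling the session with standard
#'   thresholds.
#' @return An `eye_trial_features` list: `n_saccades`, `rate` (Hz),
#'   `mean_magnitude` (deg, NaN if none), `pupil` (% of stationary mean, or
#'   NULL), `window_length` (s), `eye_absent` flag.
#' @export
eye_features <- function(session, labels = split_by_running(session)) {
  if (is.null(session$saccade_times)) {
    return(structure(list(eye_absent = TRUE), class = "eye_trial_features"))
  }
  lo <- session$trial_onsets - 0.2
  hi <- session$trial_offsets + 0.1
  nt <- n_trials(session)
  n_sacc <- integer(nt)
  mean_mag <- rep(NaN, nt)
  st <- session$saccade_times
  sm <- session$saccade_magnitudes
  for (t in seq_len(nt)) {
    inwin <- st >= lo[t] & st <= hi[t]
    n_sacc[t] <- sum(inwin)
    if (n_sacc[t] > 0) mean_mag[t] <- mean(sm[inwin])
  }
  pupil <- NULL
  if (!is.null(session$pupil)) {
    stat_mean <- mean(session$pupil[labels$label == "stationary"])
    pupil <- 100 * session$pupil / stat_mean
  }
  structure(list(eye_absent = FALSE, n_saccades = n_sacc,
                 rate = n_sacc / (hi - lo), mean_magnitude = mean_mag,
                 pupil = pupil, window_length = hi - lo),
            class = "eye_trial_features")
}

#' Compare eye-movement features between running states
#'
#' Group means with percentile-bootstrap 95% confidence intervals for
#' saccade rate, saccade magnitude (over trials that contained saccades),
#' and pupil size; the pupil difference is also reported in percent relative
#' to stationary.
#'
#' @param features [eye_features()] output.
#' @param labels [split_by_running()] output.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return Data frame with one row per measure (`saccade_rate`,
#'   `saccade_magnitude`, `pupil`): running/stationary means and CIs, and
#'   the relative difference in % with its CI.
#' @export
eye_state_comparison <- function(features, labels, n_boot = 2000, seed = 1L) {
  if (features$eye_absent) stop("eye data absent")
  run <- labels$label == "running"
  stat <- labels$label == "stationary"
  if (!any(run) || !any(stat)) stop("a running-state group is empty")
  boot_ci <- function(x, n_boot) {
    bm <- matrix(sample(x, length(x) * n_boot, replace = TRUE), ncol = n_boot)
    colMeans(bm)
  }
  one <- function(x, name) {
    xr <- x[run & !is.nan(x)]; xs <- x[stat & !is.nan(x)]
    br <- boot_ci(xr, n_boot); bs <- boot_ci(xs, n_boot)
    rel <- 100 * (br / bs - 1)
    data.frame(measure = name,
               mean_running = mean(xr), mean_stationary = mean(xs),
               ci_low_running = stats::quantile(br, 0.025),
               ci_high_running = stats::quantile(br, 0.975),
               ci_low_stationary = stats::quantile(bs, 0.025),
               ci_high_stationary = stats::quantile(bs, 0.975),
               rel_diff_pct = 100 * (mean(xr) / mean(xs) - 1),
               rel_diff_ci_low = stats::quantile(rel, 0.025),
               rel_diff_ci_high = stats::quantile(rel, 0.975),
               row.names = NULL)
  }
  with_seed(seed, {
    out <- rbind(one(features$rate, "saccade_rate"),
                 one(features$mean_magnitude, "saccade_magnitude"))
    if (!is.null(features$pupil)) out <- rbind(out, one(features$pupil, "pupil"))
    out
  })
}

#' Saccade-attributable firing-rate change between running states
#'
#' Regresses each unit's trial rate on its trial's saccade count (and,
#' optionally, mean saccade magnitude with a no-saccade indicator keeping
#' the design full rank), then multiplies the coefficients by the
#' running-minus-stationary difference in mean features. The aggregate over
#' units is the spike-rate change (Hz) attributable to the running-related
#' difference in eye movements, also expressed as a percentage gain relative
#' to the mean stationary rate.
#'
#' @param rates Trial x unit rate matrix.
#' @param features [eye_features()] output.
#' @param labels [split_by_running()] output; each state must have >= 50
#'   trials.
#' @param include_magnitude Include the magnitude regressor (default TRUE).
#' @return List: `per_unit` (predicted change per unit, Hz),
#'   `predicted_change_hz` (mean over units), `predicted_gain_pct`,
#'   `delta_features`, `magnitude_dropped` flag.
#' @export
saccade_rate_prediction <- function(rates, features, labels,
                                    include_magnitude = TRUE) {
  if (features$eye_absent) stop("eye data absent")
  run <- labels$label == "running"
  stat <- labels$label == "stationary"
  if (sum(run) < 50 || sum(stat) < 50) stop("need >= 50 trials per state")
  use <- run | stat
  mag0 <- ifelse(is.nan(features$mean_magnitude), 0, features$mean_magnitude)
  no_sacc <- as.numeric(features$n_saccades == 0)
  X <- if (include_magnitude)
    cbind(1, features$n_saccades, mag0, no_sacc)
  else cbind(1, features$n_saccades)
  dropped <- FALSE
  if (qr(X[use, , drop = FALSE])$rank < ncol(X)) {
    X <- cbind(1, features$n_saccades)
    dropped <- TRUE
    if (qr(X[use, , drop = FALSE])$rank < ncol(X))
      stop("rank-deficient saccade design even without magnitude")
  }
  delta <- colMeans(X[run, , drop = FALSE]) - colMeans(X[stat, , drop = FALSE])
  per_unit <- vapply(seq_len(ncol(rates)), function(i) {
    sel <- use & !is.na(rates[, i])
    beta <- qr.coef(qr(X[sel, , drop = FALSE]), rates[sel, i])
    beta[is.na(beta)] <- 0
    sum(beta * delta)
  }, numeric(1))
  stat_rate <- mean(rates[stat, ], na.rm = TRUE)
  list(per_unit = per_unit,
       predicted_change_hz = mean(per_unit),
       predicted_gain_pct = 100 * mean(per_unit) / stat_rate,
       delta_features = delta, magnitude_dropped = dropped)
}
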