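#' Label trials as running, stationary, or ambiguous
#'
#' A hysteresis pair of thresholds splits trials by mean treadmill speed:
#' running at or above `threshold_run`, stationary at or below
#' `threshold_stat`, and an ambiguous dead zone in between that is excluded
#' from both groups so that label noise near a single cutoff cannot dominate
#' small effects.
#'
#' @param session A `session_data` object.
#' @param threshold_run Running threshold, cm/s (default 3).
#' @param threshold_stat Stationary threshold, cm/s (default 1).
#' @return A `running_labels` list: `label` (factor with levels running /
#'   stationary / ambiguous), `threshold_run`, `threshold_stat`.
#' @export
split_by_running <- function(session, threshold_run = 3, threshold_stat = 1) {
  if (threshold_run < 0 || threshold_stat < 0) stop("negative threshold")
  if (threshold_stat > threshold_run)
    stop("threshold_stat must not exceed threshold_run")
  sp <- session$running_speed
  lab <- ifelse(sp >= threshold_run, "running",
                ifelse(sp <= threshold_stat, "stationary", "ambiguous"))
  structure(list(label = factor(lab, c("running", "stationary", "ambiguous")),
                 threshold_run = threshold_run,
                 threshold_stat = threshold_stat),
            class = "running_labels")
}

boot_mean_diff <- function(x_run, x_stat, n_boot) {
  br <- matrix(sample(x_run, length(x_run) * n_boot, replace = TRUE),
               ncol = n_boot)
  bs <- matrix(sample(x_stat, length(x_stat) * n_boot, replace = TRUE),
               ncol = n_boot)
  colMeans(br) - colMeans(bs)
}

#' Per-unit running modulation
#'
#' For each unit, compares mean firing rate on running versus stationary
#' trials, either over all stimuli or restricted to the unit's preferred
#' orientation (both drift directions and all spatial frequencies). The
#' modulation ratio is the quotient of the two group means, each floored at
#' `eps_rate` to keep the ratio finite for near-silent groups (floored units
#' are flagged). Significance comes from a percentile bootstrap of the
#' difference of group means: a unit is a significant increase (decrease)
#' when the 95% interval lies entirely above (below) zero.
#'
#' @param session A `session_data` object (needed for trial conditions).
#' @param rates Trial x unit rate matrix from [trial_rates()].
#' @param labels [split_by_running()] output.
#' @param curves Tuning curves from [compute_tuning()]; required for
#'   `scope = "preferred_stimulus"`.
#' @param scope `"all_stimuli"` or `"preferred_stimulus"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param min_trials Minimum trials per group; units under it are skipped
#'   with a reason (default 10).
#' @param eps_rate Rate floor for the ratio denominator/numerator, Hz.
#' @param seed Integer seed for the bootstrap.
#' @return A `modulation_result` data frame, one row per unit: `unit_id`,
#'   `n_run`, `n_stat`, `rate_run`, `rate_stat`, `ratio`, `ci_low`,
#'   `ci_high` (bootstrap CI on the mean difference, Hz),
#'   `significant_increase`, `significant_decrease`, `floored`, `skipped`,
#'   `reason`, `scope`.
#' @export
unit_modulation <- function(session, rates, labels, curves = NULL,
                            scope = c("all_stimuli", "preferred_stimulus"),
                            n_boot = 2000, min_trials = 10, eps_rate = 0.1,
                            seed = 1L) {
  scope <- match.arg(scope)
  if (scope == "preferred_stimulus" && is.null(curves))
    stop("preferred_stimulus scope requires tuning curves")
  lab <- labels$label
  rows <- with_seed(seed, lapply(seq_len(ncol(rates)), function(i) {
    r <- rates[, i]
    keep <- !is.na(r)
    if (scope == "preferred_stimulus") {
      pref_idx <- which(orientation_deg == curves[[i]]$preferred_orientation)
      keep <- keep & session$orientation == pref_idx
    }
    x_run <- r[keep & lab == "running"]
    x_stat <- r[keep & lab == "stationary"]
    base <- data.frame(unit_id = i, n_run = length(x_run),
                       n_stat = length(x_stat), rate_run = NA_real_,
                       rate_stat = NA_real_, ratio = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       significant_increase = FALSE,
                       significant_decrease = FALSE, floored = FALSE,
                       skipped = TRUE, reason = "", scope = scope)
    if (length(x_run) < min_trials || length(x_stat) < min_trials) {
      base$reason <- sprintf("fewer than %d trials in a group (%d running, %d stationary)",
                             min_trials, length(x_run), length(x_stat))
      return(base)
    }
    m_run <- mean(x_run); m_stat <- mean(x_stat)
    floored <- m_run < eps_rate || m_stat < eps_rate
    ratio <- max(m_run, eps_rate) / max(m_stat, eps_rate)
    bd <- boot_mean_diff(x_run, x_stat, n_boot)
    ci <- unname(stats::quantile(bd, c(0.025, 0.975)))
    base$rate_run <- m_run; base$rate_stat <- m_stat; base$ratio <- ratio
    base$ci_low <- ci[1]; base$ci_high <- ci[2]
    base$significant_increase <- ci[1] > 0
    base$significant_decrease <- ci[2] < 0
    base$floored <- floored; base$skipped <- FALSE
    base
  }))
  out <- do.call(rbind, rows)
  class(out) <- c("modulation_result", class(out))
  out
}

#' Aggregate modulation ratios across units
#'
#' Summarizes a population of per-unit running/stationary ratios by their
#' geometric mean `exp(mean(log(ratio)))` with a bootstrap-over-units 95%
#' confidence interval, together with counts of individually significant
#' increases and decreases. The log-ratios are returned for rank-based
#' cross-group comparisons.
#'
#' @param results A `modulation_result` data frame ([unit_modulation()]).
#' @param n_boot Bootstrap resamples over units (default 2000).
#' @param seed Integer seed.
#' @return List: `geometric_mean`, `ci_low`, `ci_high`, `n`,
#'   `n_significant_increase`, `n_significant_decrease`, `log_ratios`.
#' @export
aggregate_modulation <- function(results, n_boot = 2000, seed = 1L) {
  ok <- !results$skipped
  if (!any(ok)) stop("no units with a modulation ratio")
  lr <- log(results$ratio[ok])
  gm <- exp(mean(lr))
  ci <- with_seed(seed, {
    bm <- matrix(sample(lr, length(lr) * n_boot, replace = TRUE), ncol = n_boot)
    exp(unname(stats::quantile(colMeans(bm), c(0.025, 0.975))))
  })
  list(geometric_mean = gm, ci_low = ci[1], ci_high = ci[2], n = sum(ok),
       n_significant_increase = sum(results$significant_increase[ok]),
       n_significant_decrease = sum(results$significant_decrease[ok]),
       log_ratios = lr)
}
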