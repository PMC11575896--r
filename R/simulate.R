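#' Configuration for a synthetic recording session
#'
#' The generator emulates the structure of trial-based drifting-grating
#' experiments in V1: 12 orientations x 3 spatial frequencies x 2 drift
#' speeds drawn uniformly per trial, 0.833 s presentations, bout-structured
#' bimodal running behaviour, a smooth shared gain latent coupled to running,
#' slow multiplicative-free additive baseline drift built on a tent basis,
#' Poisson spike counts, and running-state-dependent saccade rate/magnitude
#' and pupil size.
#'
#' The per-trial latent is
#' `z(t) = gain_sd * v(t) / sd(v)` with
#' `v(t) = gain_running_coupling * zscore(speed(t)) + eta(t)`, where `eta` is
#' an AR(1) over trials (phi = 0.8, unit marginal variance) so that the
#' latent — and hence population activity — is autocorrelated, which is what
#' the circular-shift permutation test must cope with. A coupling of `+1`
#' gives a mouse-like session (about half the latent variance tracks
#' running), `-0.1` a marmoset-like one (weak anticorrelation).
#'
#' @param n_units Number of units (default 40).
#' @param n_trials Number of trials (default 600).
#' @param gain_sd Standard deviation of the shared latent z (unitless).
#' @param gain_running_coupling Signed weight of standardized running speed
#'   in z; `+1` mouse-like, `-0.1` marmoset-like.
#' @param run_fraction Target fraction of trials in the running state, in
#'   `[0, 1)`.
#' @param run_speed_mean Mean treadmill speed on running trials, cm/s.
#' @param tuning_concentration Mean von Mises concentration (kappa) of the
#'   axial orientation tuning; per-unit kappa is Gamma-distributed around it,
#'   giving a spread of OSIs from untuned to sharply tuned.
#' @param base_rate_range Range (Hz) of per-unit peak stimulus-driven rates.
#' @param drift_amplitude Relative size of the additive slow-drift baseline;
#'   0 removes the baseline entirely.
#' @param ds_fraction Fraction of direction-selective units (adds a 1-theta
#'   tuning component on top of the axial 2-theta component).
#' @param saccade_rate_stationary,saccade_rate_running Saccade rates, Hz.
#' @param saccade_mag_stationary,saccade_mag_running Mean saccade vector
#'   magnitudes, deg.
#' @param pupil_running_gain Multiplicative pupil-size factor during running
#'   (1.08 = 8% larger).
#' @param duration Stimulus-window length per trial, s (default 0.833).
#' @param noise Count noise model; only `"poisson"` is implemented.
#' @param species Species tag stored on the emitted session.
#' @param seed Integer seed; the same `(config, seed)` always yields a
#'   bit-identical session.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_units = 40, n_trials = 600,
                       gain_sd = 1, gain_running_coupling = 1,
                       run_fraction = 0.4, run_speed_mean = 20,
                       tuning_concentration = 1.5,
                       base_rate_range = c(2, 20),
                       drift_amplitude = 0.2, ds_fraction = 0.3,
                       saccade_rate_stationary = 2.525,
                       saccade_rate_running = 2.653,
                       saccade_mag_stationary = 8.337,
                       saccade_mag_running = 9.261,
                       pupil_running_gain = 1.08,
                       duration = 0.833, noise = "poisson",
                       species = "synthetic", seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_units > 0, n_trials > 0, gain_sd >= 0,
            run_fraction >= 0, run_fraction < 1,
            length(base_rate_range) == 2, base_rate_range[1] > 0,
            drift_amplitude >= 0, drift_amplitude <= 1,
            duration > 0)
  match.arg(noise, "poisson")
  structure(cfg, class = "sim_config")
}

#' Generate bout-structured running behaviour
#'
#' Trials alternate between running and stationary bouts via a two-state
#' Markov chain whose dwell times are at least 5 trials in each state and
#' whose stationary distribution matches `run_fraction`. Running-trial speeds
#' are Gamma-distributed around `run_speed_mean`; stationary speeds are small
#' treadmill jitter near zero, giving the bimodal speed histogram typical of
#' head-fixed locomotion data.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `speed` (per-trial mean speed, cm/s), `state` (logical,
#'   TRUE = running bout) and `trace` (10 Hz speed time series covering the
#'   trial sequence).
#' @export
generate_running <- function(config, seed = config$seed) {
  f <- config$run_fraction
  nt <- config$n_trials
  with_seed(seed, {
    if (f == 0) {
      state <- rep(FALSE, nt)
    } else {
      dwell_run <- 5 * max(1, f / (1 - f))
      dwell_stat <- 5 * max(1, (1 - f) / f)
      p_exit_run <- 1 / dwell_run
      p_exit_stat <- 1 / dwell_stat
      state <- logical(nt)
      state[1] <- stats::runif(1) < f
      u <- stats::runif(nt - 1)
      for (t in 2:nt) {
        state[t] <- if (state[t - 1]) u[t - 1] >= p_exit_run else u[t - 1] < p_exit_stat
      }
    }
    speed <- numeric(nt)
    n_run <- sum(state)
    if (n_run > 0)
      speed[state] <- stats::rgamma(n_run, shape = 4,
                                    scale = config$run_speed_mean / 4)
    speed[!state] <- abs(stats::rnorm(nt - n_run, 0, 0.3))
    trial_t <- (seq_len(nt) - 0.5) * (config$duration + 0.35)
    trace_t <- seq(0, max(trial_t) + 1, by = 0.1)
    trace_v <- pmax(0, stats::approx(trial_t, speed, xout = trace_t, rule = 2)$y +
                      stats::rnorm(length(trace_t), 0, 0.2))
    list(speed = speed, state = state,
         trace = list(time = trace_t, speed = trace_v))
  })
}

# scale loadings so that 1 + z*w < 0 on at most `frac` of (trial, unit) pairs
scale_loadings <- function(z, w_raw, frac = 0.01) {
  s <- as.vector(outer(z, w_raw))
  q <- stats::quantile(s, frac, type = 1, names = FALSE)
  if (q >= -1) return(w_raw)
  w_raw * (0.999 / abs(q))
}

#' Generate a synthetic session with ground truth
#'
#' Draws grating conditions uniformly over 12 orientations x 3 spatial
#' frequencies x 2 drift speeds, builds per-unit tuning weights `A_true`
#' (von Mises in 2-theta with Gamma-distributed concentration, a fraction of
#' direction-selective units, peaked spatial-frequency profiles, and a 20%
#' untuned pedestal), a shared latent `z_true` coupled to running, loadings
#' `w_true` (scaled so the rectifier clips at most 1% of unit-trial gains),
#' and a smooth additive baseline `drift_true` on the same 5-knot tent basis
#' the model uses. Expected rates are
#' `lambda_i(t) = A_true[i, cond(t)] * ReLU(1 + z_true(t) * w_true[i]) + drift_true(t, i)`
#' and counts are Poisson with mean `lambda * duration`.
#'
#' @param config A [sim_config()].
#' @return List with elements `session` (a [session_data()]) and `truth`
#'   (class `ground_truth`: `A_true`, `w_true`, `z_true`, `drift_true`,
#'   `running_label_true`, `cond_index`).
#' @export
generate_session <- function(config) {
  cfg <- config
  nt <- cfg$n_trials
  nu <- cfg$n_units
  run <- generate_running(cfg, seed = derive_seed(cfg$seed, "running"))
  out <- with_seed(derive_seed(cfg$seed, "session"), {
    ori_idx <- sample.int(12L, nt, replace = TRUE)
    sf_idx <- sample.int(3L, nt, replace = TRUE)
    dr_idx <- sample.int(2L, nt, replace = TRUE)
    cond <- (sf_idx - 1L) * 12L + ori_idx           # 36 model conditions

    iti <- stats::runif(nt, 0.249, 0.415)
    onsets <- cumsum(c(0.5, rep(cfg$duration, nt - 1) + iti[-nt]))
    offsets <- onsets + cfg$duration

    # shared latent: coupling * standardized speed + AR(1) smooth noise
    if (cfg$gain_sd > 0) {
      sz <- if (stats::sd(run$speed) > 0)
        (run$speed - mean(run$speed)) / stats::sd(run$speed) else numeric(nt)
      phi <- 0.8
      eta <- as.numeric(stats::arima.sim(list(ar = phi), nt,
                                         innov = stats::rnorm(nt, 0, sqrt(1 - phi^2)),
                                         n.start = 50,
                                         start.innov = stats::rnorm(50, 0, sqrt(1 - phi^2))))
      v <- cfg$gain_running_coupling * sz + eta
      z_true <- cfg$gain_sd * v / stats::sd(v)
    } else {
      z_true <- numeric(nt)
    }

    w_raw <- stats::rnorm(nu, 1, 0.4)
    w_true <- if (cfg$gain_sd > 0) scale_loadings(z_true, w_raw) else w_raw * 0

    # tuning weights A_true (units x 36 conditions)
    theta <- (0:11) * 30
    kappa <- stats::rexp(nu, rate = 1 / cfg$tuning_concentration)
    theta_pref <- stats::runif(nu, 0, 180)
    peak <- stats::runif(nu, cfg$base_rate_range[1], cfg$base_rate_range[2])
    is_ds <- stats::runif(nu) < cfg$ds_fraction
    sf_pref <- sample.int(3L, nu, replace = TRUE)
    A_true <- matrix(0, nu, 36)
    for (i in seq_len(nu)) {
      d <- (theta - theta_pref[i]) * pi / 180
      prof <- exp(kappa[i] * (cos(2 * d) - 1))
      if (is_ds[i]) prof <- prof * (1 + 0.5 * cos(d)) / 1.5
      prof <- prof / max(prof)
      sfp <- exp(-(seq_len(3) - sf_pref[i])^2 / (2 * 0.8^2))
      sfp <- sfp / max(sfp)
      tune <- as.vector(outer(prof, sfp))           # ori fastest, matches cond
      A_true[i, ] <- peak[i] * (0.2 + 0.8 * tune)
    }

    # additive slow drift on the model's own 5-knot tent basis
    drift_true <- matrix(0, nt, nu)
    if (cfg$drift_amplitude > 0) {
      phi_basis <- tent_basis(onsets)$phi
      dcoef <- matrix(stats::runif(5 * nu, -1, 1), 5, nu)
      smooth <- phi_basis %*% dcoef                 # in [-1, 1]
      drift_true <- sweep(1 + 0.5 * smooth, 2, cfg$drift_amplitude * peak, "*")
    }

    gain <- pmax(0, 1 + outer(z_true, w_true))
    lambda <- t(A_true[, cond]) * gain + drift_true
    if (any(lambda < 0))
      stop("internal error: negative expected rate in generator")
    counts <- matrix(stats::rpois(nt * nu, lambda * cfg$duration), nt, nu)

    # saccades and pupil, state-dependent
    win_lo <- onsets - 0.2
    win_len <- cfg$duration + 0.3
    rate <- ifelse(run$state, cfg$saccade_rate_running, cfg$saccade_rate_stationary)
    mag_mean <- ifelse(run$state, cfg$saccade_mag_running, cfg$saccade_mag_stationary)
    n_sacc <- stats::rpois(nt, rate * win_len)
    saccade_times <- numeric(0)
    saccade_mags <- numeric(0)
    for (t in which(n_sacc > 0)) {
      saccade_times <- c(saccade_times,
                         sort(stats::runif(n_sacc[t], win_lo[t], win_lo[t] + win_len)))
      saccade_mags <- c(saccade_mags,
                        stats::rgamma(n_sacc[t], shape = 9, scale = mag_mean[t] / 9))
    }
    pupil <- 1000 * ifelse(run$state, cfg$pupil_running_gain, 1) *
      (1 + 0.05 * stats::rnorm(nt))

    session <- session_data(
      session_id = sprintf("synthetic-%d", cfg$seed), species = cfg$species,
      counts = counts, duration = rep(cfg$duration, nt),
      orientation = ori_idx, spatial_freq = sf_idx, drift_speed = dr_idx,
      running_speed = run$speed, trial_onsets = onsets, trial_offsets = offsets,
      running_trace = run$trace, saccade_times = saccade_times,
      saccade_magnitudes = saccade_mags, pupil = pupil)
    truth <- structure(list(
      A_true = A_true, w_true = w_true, z_true = z_true,
      drift_true = drift_true, running_label_true = run$state,
      cond_index = cond, peak = peak), class = "ground_truth")
    list(session = session, truth = truth)
  })
  out
}
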