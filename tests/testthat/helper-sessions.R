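# hand-built sessions with full control over counts and conditions
make_test_session <- function(counts, running_speed = NULL, orientation = NULL,
                              spatial_freq = NULL, drift_speed = NULL,
                              duration = 1, species = "synthetic",
                              saccade_times = NULL, saccade_magnitudes = NULL,
                              pupil = NULL, id = "test") {
  counts <- as.matrix(counts)
  nt <- nrow(counts)
  onsets <- seq(0.5, by = 1.5, length.out = nt)
  session_data(
    session_id = id, species = species, counts = counts,
    duration = rep(duration, nt),
    orientation = if (is.null(orientation)) rep_len(1:12, nt) else orientation,
    spatial_freq = if (is.null(spatial_freq)) rep_len(1:3, nt) else spatial_freq,
    drift_speed = if (is.null(drift_speed)) rep_len(1:2, nt) else drift_speed,
    running_speed = if (is.null(running_speed)) rep(0, nt) else running_speed,
    trial_onsets = onsets, trial_offsets = onsets + duration,
    saccade_times = saccade_times, saccade_magnitudes = saccade_magnitudes,
    pupil = pupil)
}

# independent leading-eigenvector oracle: power iteration on the covariance
power_iteration_pc1 <- function(X, n_iter = 20000, tol = 1e-30) {
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nrow(X) - 1)
  v <- rep(1 / sqrt(ncol(C)), ncol(C))
  for (i in seq_len(n_iter)) {
    v_new <- C %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sum((abs(v_new) - abs(v))^2) < tol) { v <- v_new; break }
    v <- v_new
  }
  as.numeric(v)
}

# AR(1) series for permutation-test calibration
ar1_series <- function(n, phi, sd_innov = 1) {
  as.numeric(stats::arima.sim(list(ar = phi), n,
                              innov = rnorm(n, 0, sd_innov),
                              n.start = 100,
                              start.innov = rnorm(100, 0, sd_innov)))
}
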