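#' Tent (piecewise-linear) drift basis
#'
#' Five hat functions with knots at the \{0, 25, 50, 75, 100\}% quantiles of
#' the trial times form a partition of unity used to capture slow per-unit
#' drifts in baseline firing rate.
#'
#' @param times Per-trial times (e.g., trial onsets), s.
#' @return List with `phi` (trial x 5 matrix, rows sum to 1, entries >= 0)
#'   and `knots` (the 5 knot times).
#' @export
tent_basis <- function(times) {
  knots <- unname(stats::quantile(times, c(0, 0.25, 0.5, 0.75, 1)))
  phi <- matrix(0, length(times), 5)
  for (j in 1:5) {
    v <- numeric(length(times))
    if (j > 1) {
      up <- times >= knots[j - 1] & times <= knots[j]
      v[up] <- (times[up] - knots[j - 1]) / (knots[j] - knots[j - 1])
    }
    if (j < 5) {
      down <- times > knots[j] & times <= knots[j + 1]
      v[down] <- (knots[j + 1] - times[down]) / (knots[j + 1] - knots[j])
    }
    if (j == 1) v[times <= knots[1]] <- 1
    phi[, j] <- v
  }
  list(phi = phi, knots = knots)
}

#' Stimulus and drift design matrices for a session
#'
#' The stimulus on trial t is an m-dimensional one-hot vector over the m = 36
#' orientation x spatial-frequency conditions (drift speed pooled), so the
#' stimulus response is a linear projection on the tuning weights. The drift
#' design is the 5-knot tent basis over session time.
#'
#' @param session A `session_data` object.
#' @return List with `onehot` (trial x 36), `cond_index` (per-trial 1..36),
#'   `phi` (trial x 5 tent basis), `knots`.
#' @export
build_design <- function(session) {
  cond <- (session$spatial_freq - 1L) * 12L + session$orientation
  if (any(cond < 1L | cond > 36L)) stop("unseen condition index")
  S <- matrix(0, n_trials(session), 36)
  S[cbind(seq_along(cond), cond)] <- 1
  tb <- tent_basis(session$trial_onsets)
  list(onehot = S, cond_index = cond, phi = tb$phi, knots = tb$knots)
}

#' Speckled holdout masks
#'
#' Cross-validation masks at the level of individual (trial, unit) cells:
#' each cell is held out independently with probability `p_holdout`, so every
#' trial retains observed units and the latent can still be estimated on
#' held-out cells' trials. Held-out cells are split 50/50 into a validation
#' set (used to stop optimization) and a test set (used only for evaluation).
#'
#' @param n_trials,n_units Matrix dimensions.
#' @param p_holdout Holdout probability per cell, in `(0, 0.5]`.
#' @param seed Integer seed.
#' @return A `speckled_split` list of three logical trial x unit masks
#'   `train`, `validation`, `test` that partition all cells.
#' @export
speckled_split <- function(n_trials, n_units, p_holdout = 0.25, seed = 1L) {
  if (p_holdout <= 0 || p_holdout > 0.5) stop("p_holdout must be in (0, 0.5]")
  with_seed(seed, {
    held <- matrix(stats::runif(n_trials * n_units) < p_holdout,
                   n_trials, n_units)
    to_val <- matrix(stats::runif(n_trials * n_units) < 0.5,
                     n_trials, n_units)
    structure(list(train = !held, validation = held & to_val,
                   test = held & !to_val, p_holdout = p_holdout),
              class = "speckled_split")
  })
}

# per-unit ridge solve for X = [onehot | phi]; penalty (scaled to the mean
# square of the 36 tuning weights) applies to the stimulus columns only --
# the 5 drift weights get a negligible jitter for invertibility
ridge_unit <- function(X, y, rows, l2) {
  Xr <- X[rows, , drop = FALSE]
  yr <- y[rows]
  nr <- length(yr)
  D <- diag(c(rep(l2 / 36, 36), rep(1e-8, 5)))
  beta <- solve(crossprod(Xr) / nr + D, crossprod(Xr, yr) / nr)
  as.numeric(beta)
}

r2_on_cells <- function(obs, pred, mask) {
  vapply(seq_len(ncol(obs)), function(i) {
    sel <- mask[, i] & !is.na(obs[, i])
    if (sum(sel) < 3) return(NA_real_)
    y <- obs[sel, i]
    if (stats::var(y) == 0) return(0)
    1 - mean((y - pred[sel, i])^2) / stats::var(y) * (length(y) - 1) / length(y)
  }, numeric(1))
}

#' Fit the stimulus + slow-drift baseline model
#'
#' The baseline ("no latent") model predicts each unit's rate as
#' `A s(t) + B phi(t)`: a per-condition mean plus a smooth drift. Each unit
#' is fitted by ridge regression on its training cells, with the L2 penalty
#' on the tuning weights chosen from a small grid by 5-fold cross-validation
#' within the training cells (one penalty per session, pooled across units).
#' A drift-only null model (`B phi(t)` alone) is fitted alongside; units
#' whose test-cell variance explained beats the null are the ones counted
#' toward session inclusion in model summaries.
#'
#' @param session A `session_data` object.
#' @param design [build_design()] output.
#' @param split [speckled_split()] output.
#' @param l2_grid Candidate L2 penalties (scaled to mean-square weight).
#' @param seed Seed for the CV fold assignment.
#' @return A `baseline_fit` list: `A` (units x 36, Hz), `B` (units x 5, Hz),
#'   `l2`, `prediction` (trial x unit), `r2_baseline`, `r2_drift`,
#'   `beats_null` (per unit), `rates`.
#' @export
fit_baseline <- function(session, design, split,
                         l2_grid = 10^seq(-4, -1), seed = 1L) {
  R <- trial_rates(session)
  X <- cbind(design$onehot, design$phi)
  nu <- ncol(R); nt <- nrow(R)
  if (length(l2_grid) > 1) {
    folds <- with_seed(derive_seed(seed, "baseline-cv"),
                       matrix(sample.int(5, nt * nu, replace = TRUE), nt, nu))
    cv_err <- vapply(l2_grid, function(l2) {
      tot <- 0; nc <- 0
      for (k in 1:5) {
        for (i in seq_len(nu)) {
          tr <- split$train[, i] & !is.na(R[, i]) & folds[, i] != k
          te <- split$train[, i] & !is.na(R[, i]) & folds[, i] == k
          if (sum(tr) < 45 || sum(te) < 1) next
          beta <- ridge_unit(X, R[, i], tr, l2)
          tot <- tot + sum((R[te, i] - X[te, , drop = FALSE] %*% beta)^2)
          nc <- nc + sum(te)
        }
      }
      tot / nc
    }, numeric(1))
    l2 <- l2_grid[which.min(cv_err)]
  } else l2 <- l2_grid
  A <- matrix(0, nu, 36); B <- matrix(0, nu, 5)
  pred <- matrix(NA_real_, nt, nu)
  drift_pred <- matrix(NA_real_, nt, nu)
  for (i in seq_len(nu)) {
    tr <- split$train[, i] & !is.na(R[, i])
    if (sum(tr) < 42)
      stop("fewer training cells than parameters for unit ", i)
    beta <- ridge_unit(X, R[, i], tr, l2)
    A[i, ] <- beta[1:36]; B[i, ] <- beta[37:41]
    pred[, i] <- X %*% beta
    # drift-only null
    Phi_r <- design$phi[tr, , drop = FALSE]
    bnull <- solve(crossprod(Phi_r) + diag(1e-8, 5), crossprod(Phi_r, R[tr, i]))
    drift_pred[, i] <- design$phi %*% bnull
  }
  r2_b <- r2_on_cells(R, pred, split$test)
  r2_d <- r2_on_cells(R, drift_pred, split$test)
  structure(list(A = A, B = B, l2 = l2, prediction = pred,
                 r2_baseline = r2_b, r2_drift = r2_d,
                 beats_null = !is.na(r2_b) & !is.na(r2_d) & r2_b > r2_d,
                 rates = R),
            class = "baseline_fit")
}

#' Rank-1 autoencoder initialization of the latent and loadings
#'
#' A rank-1 linear reconstruction of the training-cell residuals (observed
#' rate minus baseline prediction): alternating least squares on the
#' incomplete matrix, at most `max_iter` sweeps. The loadings' sign is
#' anchored so their signs sum non-negatively and the latent is scaled to
#' unit variance.
#'
#' @param residuals Trial x unit residual matrix with `NA` at cells that are
#'   not training cells.
#' @param max_iter Maximum ALS sweeps (default 100).
#' @return List with `z0` (per-trial latent, unit variance) and `w0`
#'   (per-unit loadings; 0 for all-missing units).
#' @export
init_autoencoder <- function(residuals, max_iter = 100) {
  Rm <- as.matrix(residuals)
  M <- !is.na(Rm)
  R0 <- Rm; R0[!M] <- 0
  nt <- nrow(R0); nu <- ncol(R0)
  # warm start from the leading right singular vector of the zero-filled matrix
  w <- svd(R0, nu = 0, nv = 1)$v[, 1]
  z <- numeric(nt)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    den_z <- as.numeric(M %*% (w^2))
    z <- as.numeric(R0 %*% w) / ifelse(den_z > 0, den_z, 1)
    den_w <- as.numeric(crossprod(M, z^2))
    w <- as.numeric(crossprod(R0, z)) / ifelse(den_w > 0, den_w, 1)
    w[colSums(M) == 0] <- 0
    err <- sum((R0 - tcrossprod(z, w) * M)^2)
    if (abs(prev - err) < 1e-12 * (1 + err)) break
    prev <- err
  }
  s <- sign0(sum(sign0(w)))
  w <- s * w; z <- s * z
  if (stats::sd(z) > 0) {
    w <- w * stats::sd(z)
    z <- (z - 0) / stats::sd(z)
  }
  list(z0 = z, w0 = w)
}

# ---- gain model objective --------------------------------------------------

pack_params <- function(A, w, z, B) c(as.numeric(A), w, z, as.numeric(B))

unpack_params <- function(par, nu, nt) {
  list(A = matrix(par[seq_len(nu * 36)], nu, 36),
       w = par[nu * 36 + seq_len(nu)],
       z = par[nu * 36 + nu + seq_len(nt)],
       B = matrix(par[nu * 36 + nu + nt + seq_len(nu * 5)], nu, 5))
}

# closure over the data; fn/gr operate on the packed parameter vector.
# loss = mean over training cells of squared error
#      + l2 * (mean(A^2) + mean(w^2)) + smooth_z * mean(diff(z)^2)
make_gain_objective <- function(R, M, cond, S, Phi, l2, smooth_z) {
  R0 <- R; R0[!M] <- 0
  nt <- nrow(R); nu <- ncol(R)
  Ntr <- sum(M)
  fn <- function(par) {
    p <- unpack_params(par, nu, nt)
    Stim <- t(p$A[, cond, drop = FALSE])
    G <- 1 + tcrossprod(p$z, p$w)
    P <- Stim * pmax(G, 0) + Phi %*% t(p$B)
    E <- (P - R0) * M
    sum(E * E) / Ntr + l2 * (mean(p$A^2) + mean(p$w^2)) +
      smooth_z * mean(diff(p$z)^2)
  }
  gr <- function(par) {
    p <- unpack_params(par, nu, nt)
    Stim <- t(p$A[, cond, drop = FALSE])
    G <- 1 + tcrossprod(p$z, p$w)
    act <- G > 0
    P <- Stim * (G * act) + Phi %*% t(p$B)
    E <- (P - R0) * M
    W2 <- 2 * E / Ntr
    gA <- crossprod(W2 * (G * act), S) + 2 * l2 * p$A / (nu * 36)
    H <- W2 * Stim * act
    gw <- as.numeric(crossprod(H, p$z)) + 2 * l2 * p$w / nu
    d <- diff(p$z)
    gz <- as.numeric(H %*% p$w) +
      2 * smooth_z * (c(0, d) - c(d, 0)) / (nt - 1)
    gB <- crossprod(W2, Phi)
    pack_params(gA, gw, gz, gB)
  }
  list(fn = fn, gr = gr, Ntr = Ntr)
}

mse_on_mask <- function(R, pred, mask) {
  sel <- mask & !is.na(R)
  mean((pred[sel] - R[sel])^2)
}

gain_prediction <- function(A, w, z, B, cond, Phi) {
  t(A[, cond, drop = FALSE]) * pmax(1 + tcrossprod(z, w), 0) + Phi %*% t(B)
}

# ---- initialization refinement --------------------------------------------
# The rank-1 autoencoder works in residual units, so its loadings confound
# the gain loading with each unit's mean stimulus drive, and a naive
# regression against fitted tuning curves is attenuated by co-adaptation of
# the tuning estimate with the gain. These moment-based refinements avoid
# both: the loading estimator uses within-condition contrasts with
# leave-one-out condition means (no tuning-curve estimate enters, and no
# trial influences its own reference), and the latent update is an exact
# per-trial regression given gain-corrected tuning fits.

loo_contrast_w <- function(R, Mtr, cond, z) {
  vapply(seq_len(ncol(R)), function(i) {
    rows <- which(Mtr[, i])
    if (length(rows) < 10) return(0)
    cc <- as.character(cond[rows]); Ri <- R[rows, i]; zi <- z[rows]
    nS <- tapply(Ri, cc, sum)[cc]
    nZ <- tapply(zi, cc, sum)[cc]
    nC <- tapply(Ri, cc, length)[cc]
    keep <- nC > 1
    if (!any(keep)) return(0)
    Rloo <- (nS[keep] - Ri[keep]) / (nC[keep] - 1)
    zloo <- (nZ[keep] - zi[keep]) / (nC[keep] - 1)
    x <- Rloo * (zi[keep] - zloo)
    y <- Ri[keep] - Rloo
    sum(x * y) / (sum(x * x) + 1e-8)
  }, numeric(1))
}

refit_AB_given_gain <- function(R, Mtr, onehot, Phi, gain) {
  nu <- ncol(R)
  A <- matrix(0, nu, 36); B <- matrix(0, nu, 5)
  for (i in seq_len(nu)) {
    rows <- Mtr[, i]
    Xi <- cbind(onehot[rows, , drop = FALSE] * gain[rows, i],
                Phi[rows, , drop = FALSE])
    beta <- solve(crossprod(Xi) + diag(1e-6, 41), crossprod(Xi, R[rows, i]))
    A[i, ] <- beta[1:36]; B[i, ] <- beta[37:41]
  }
  list(A = A, B = B)
}

z_regression <- function(R, Mtr, A, B, w, cond, Phi, z_prev) {
  Stim <- t(A[, cond, drop = FALSE])
  Drift <- Phi %*% t(B)
  act <- (1 + outer(z_prev, w)) > 0
  vapply(seq_len(nrow(R)), function(t) {
    cols <- Mtr[t, ] & act[t, ]
    if (!any(cols)) return(0)
    x <- Stim[t, cols] * w[cols]
    y <- R[t, cols] - Stim[t, cols] - Drift[t, cols]
    sum(x * y) / (sum(x * x) + 1e-8)
  }, numeric(1))
}

refine_init <- function(R, Mtr, onehot, cond, Phi, z0, n_iter = 2) {
  z <- z0
  w <- numeric(ncol(R))
  A <- NULL; B <- NULL
  for (it in seq_len(n_iter)) {
    w <- loo_contrast_w(R, Mtr, cond, z)
    ab <- refit_AB_given_gain(R, Mtr, onehot, Phi, pmax(1 + outer(z, w), 0))
    A <- ab$A; B <- ab$B
    z <- z_regression(R, Mtr, A, B, w, cond, Phi, z)
  }
  ab <- refit_AB_given_gain(R, Mtr, onehot, Phi, pmax(1 + outer(z, w), 0))
  list(A = ab$A, B = ab$B, w = w, z = z)
}

# L-BFGS in blocks with validation-based early stopping
run_gain_opt <- function(par0, obj, val_fn, max_iter, block = 25, patience = 3) {
  par <- par0
  best_par <- par0
  best_val <- val_fn(par0)
  init_val <- best_val
  bad <- 0
  n_blocks <- ceiling(max_iter / block)
  for (b in seq_len(n_blocks)) {
    o <- stats::optim(par, obj$fn, obj$gr, method = "L-BFGS-B",
                      control = list(maxit = block, factr = 1e4))
    if (!is.finite(o$value))
      stop("non-finite loss at optimization block ", b)
    par <- o$par
    v <- val_fn(par)
    if (v < best_val - 1e-12) {
      best_val <- v; best_par <- par; bad <- 0
    } else bad <- bad + 1
    if (bad >= patience) break
    if (o$convergence == 0 && b > 1) break
  }
  list(par = best_par, val = best_val, reverted = !(best_val < init_val))
}

#' Fit the shared multiplicative-gain model
#'
#' Fits `r(t) = A s(t) * ReLU(1 + z(t) w) + B phi(t)` to a session's trial
#' rates by minimizing mean squared error on the training cells of a
#' speckled split with L-BFGS and analytic gradients. The latent is
#' initialized from a rank-1 autoencoder on the baseline residuals; because
#' the autoencoder works in residual units, the initialization is then
#' refined into gain units by a leave-one-out within-condition contrast
#' regression for the loadings (which keeps tuning-curve estimation error
#' out of the loading estimate), exact per-unit tuning/drift refits given
#' the gain, and a per-trial latent regression, iterated twice. The L2
#' penalty on `A` and `w` is selected from a grid using a held-out subset of
#' training cells; the latent carries a small fixed squared-difference
#' smoothness penalty. Validation-cell MSE is monitored every optimization
#' block; if it never improves on the initialization the fit reverts to the
#' initialization. After fitting, the latent/loadings sign is anchored so
#' loading signs sum non-negatively, and the latent is rescaled to unit
#' variance (the loadings absorb the scale; predictions are unchanged).
#'
#' @param session A `session_data` object.
#' @param design [build_design()] output.
#' @param split [speckled_split()] output.
#' @param baseline Optional [fit_baseline()] result (computed if missing).
#' @param init Optional list `(z0, w0)` (computed if missing).
#' @param l2_grid Candidate L2 penalties for `A` and `w`.
#' @param smooth_z Smoothness penalty on the latent; one small value shared
#'   across sessions (default 1e-3).
#' @param max_iter Total L-BFGS iteration budget (default 500, in blocks of
#'   25 with patience 3 on validation MSE).
#' @param labels Optional [split_by_running()] output; if given, running
#'   gain statistics are filled in via [gain_statistics()].
#' @param seed Integer seed (inner tuning split).
#' @return List with `params` (a `gain_model_params`: `A`, `w`, `z`, `B`,
#'   `hyper`) and `result` (a `gain_fit_result`: per-unit `r2_baseline`,
#'   `r2_gain`, `r2_drift`, medians, `pop_gain`, `gain_sd`,
#'   `gain_diff_running`, `reverted_to_init`, `n_beat_null`).
#' @export
fit_gain <- function(session, design, split, baseline = NULL, init = NULL,
                     l2_grid = 10^seq(-4, -1), smooth_z = 1e-3,
                     max_iter = 500, labels = NULL, seed = 1L) {
  if (is.null(baseline))
    baseline <- fit_baseline(session, design, split, l2_grid, seed = seed)
  R <- baseline$rates
  nt <- nrow(R); nu <- ncol(R)
  Mtr <- split$train & !is.na(R)
  Mval <- split$validation & !is.na(R)
  if (is.null(init)) {
    resid <- R - baseline$prediction
    resid[!Mtr] <- NA
    init <- init_autoencoder(resid)
  }
  cond <- design$cond_index; S <- design$onehot; Phi <- design$phi
  ref <- refine_init(R, Mtr, S, cond, Phi, init$z0)
  par0 <- pack_params(ref$A, ref$w, ref$z, ref$B)

  val_fn_for <- function(Mask) {
    function(par) {
      p <- unpack_params(par, nu, nt)
      mse_on_mask(R, gain_prediction(p$A, p$w, p$z, p$B, cond, Phi), Mask)
    }
  }

  if (length(l2_grid) > 1) {
    tune_mask <- with_seed(derive_seed(seed, "l2-tune"),
                           matrix(stats::runif(nt * nu) < 0.2, nt, nu)) & Mtr
    Mtune_train <- Mtr & !tune_mask
    tune_err <- vapply(l2_grid, function(l2) {
      obj <- make_gain_objective(R, Mtune_train, cond, S, Phi, l2, smooth_z)
      fit <- run_gain_opt(par0, obj, val_fn_for(Mval), max_iter = 100)
      val_fn_for(tune_mask)(fit$par)
    }, numeric(1))
    l2 <- l2_grid[which.min(tune_err)]
  } else l2 <- l2_grid

  obj <- make_gain_objective(R, Mtr, cond, S, Phi, l2, smooth_z)
  fit <- run_gain_opt(par0, obj, val_fn_for(Mval), max_iter = max_iter)
  p <- unpack_params(fit$par, nu, nt)

  # sign anchoring and unit-variance latent (prediction-preserving)
  s <- sign0(sum(sign0(p$w)))
  p$w <- s * p$w; p$z <- s * p$z
  if (stats::sd(p$z) > 0 && any(p$w != 0)) {
    sc <- stats::sd(p$z)
    p$w <- p$w * sc; p$z <- p$z / sc
  }
  params <- structure(list(A = p$A, w = p$w, z = p$z, B = p$B,
                           hyper = list(l2 = l2, smooth_z = smooth_z)),
                      class = "gain_model_params")
  pred <- gain_prediction(p$A, p$w, p$z, p$B, cond, Phi)
  r2_gain <- r2_on_cells(R, pred, split$test)
  pop_gain <- rowMeans(pmax(1 + tcrossprod(p$z, p$w), 0))
  result <- structure(list(
    r2_baseline = baseline$r2_baseline, r2_gain = r2_gain,
    r2_drift = baseline$r2_drift,
    session_r2 = list(baseline = stats::median(baseline$r2_baseline, na.rm = TRUE),
                      gain = stats::median(r2_gain, na.rm = TRUE)),
    pop_gain = pop_gain, gain_sd = stats::sd(pop_gain),
    gain_diff_running = NA_real_, gain_diff_t = NA_real_,
    reverted_to_init = fit$reverted, l2 = l2,
    n_beat_null = sum(baseline$beats_null)),
    class = "gain_fit_result")
  if (!is.null(labels)) result <- gain_statistics(params, result, labels)
  list(params = params, result = result)
}

#' Running-state statistics of the shared gain
#'
#' Projects the latent back to population space as the per-trial
#' population-average gain `pop_gain(t) = mean_i ReLU(1 + z(t) w_i)` and
#' summarizes it: its standard deviation over trials and its mean difference
#' between running and stationary trials (ambiguous trials excluded), with a
#' Welch t statistic on the per-trial values.
#'
#' @param params A `gain_model_params`.
#' @param result A `gain_fit_result` to update.
#' @param labels [split_by_running()] output.
#' @return The updated `gain_fit_result` (`pop_gain`, `gain_sd`,
#'   `gain_diff_running`, `gain_diff_t`; the difference is `NA` with a
#'   warning when either state has no trials).
#' @export
gain_statistics <- function(params, result, labels) {
  g <- rowMeans(pmax(1 + tcrossprod(params$z, params$w), 0))
  result$pop_gain <- g
  result$gain_sd <- stats::sd(g)
  run <- labels$label == "running"
  stat <- labels$label == "stationary"
  if (!any(run) || !any(stat)) {
    warning("a running-state group is empty; gain_diff_running undefined")
    result$gain_diff_running <- NA_real_
    result$gain_diff_t <- NA_real_
    return(result)
  }
  result$gain_diff_running <- mean(g[run]) - mean(g[stat])
  result$gain_diff_t <- tryCatch(
    unname(stats::t.test(g[run], g[stat])$statistic), error = function(e) NA_real_)
  result
}
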