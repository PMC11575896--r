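test_that("stimulus design is one-hot and the tent basis interpolates", {
  g <- generate_session(sim_config(n_units = 5, n_trials = 200, seed = 3))
  d <- build_design(g$session)
  expect_true(all(rowSums(d$onehot) == 1))
  expect_equal(d$onehot[cbind(1:200, d$cond_index)], rep(1, 200))
  expect_equal(d$cond_index,
               (g$session$spatial_freq - 1L) * 12L + g$session$orientation)

  tb <- tent_basis(seq(0, 100, by = 0.5))
  expect_equal(tb$knots, c(0, 25, 50, 75, 100))
  expect_equal(tb$phi[1, ], c(1, 0, 0, 0, 0))
  expect_equal(tb$phi[which(seq(0, 100, by = 0.5) == 37.5), ],
               c(0, 0.5, 0.5, 0, 0), tolerance = 1e-12)
  expect_true(all(abs(rowSums(tb$phi) - 1) < 1e-12))
  expect_true(all(tb$phi >= 0))
})

test_that("speckled masks partition cells at the requested rate", {
  expect_error(speckled_split(10, 10, p_holdout = 0), "p_holdout")
  sp <- speckled_split(200, 50, p_holdout = 0.25, seed = 8)
  tot <- sp$train + sp$validation + sp$test
  expect_true(all(tot == 1))
  frac <- 1 - mean(sp$train)
  expect_gte(frac, 0.23); expect_lte(frac, 0.27)
  expect_identical(speckled_split(200, 50, 0.25, seed = 8), sp)
})

test_that("baseline model exactly fits noiseless stimulus + drift data", {
  nt <- 720
  ori <- rep_len(1:12, nt); sf <- rep_len(rep(1:3, each = 12), nt)
  A_true <- matrix(2L * (1:36), 1, 36)
  cond <- (sf - 1L) * 12L + ori
  cnt <- matrix(A_true[1, cond], ncol = 1)
  s <- make_test_session(cnt, orientation = ori, spatial_freq = sf)
  d <- build_design(s)
  sp <- speckled_split(nt, 1, 0.25, seed = 2)
  fit <- fit_baseline(s, d, sp, l2_grid = 1e-8)
  pred_cond <- fit$A[1, cond] + as.numeric(d$phi %*% fit$B[1, ])
  expect_lt(max(abs(pred_cond - A_true[1, cond])), 1e-3)
  expect_gt(fit$r2_baseline[1], 0.999)
})

test_that("constant-rate units get a flat tuning row and zero r2", {
  nt <- 600
  s <- make_test_session(matrix(5L, nt, 2))
  d <- build_design(s)
  sp <- speckled_split(nt, 2, 0.25, seed = 4)
  fit <- fit_baseline(s, d, sp, l2_grid = 1e-6)
  pred <- fit$A[1, d$cond_index] + as.numeric(d$phi %*% fit$B[1, ])
  expect_lt(max(pred) - min(pred), 1e-6)
  expect_equal(fit$r2_baseline[1], 0)
})

test_that("baseline test r2 approaches the explainable-variance bound", {
  cfg <- sim_config(n_units = 10, n_trials = 5000, gain_sd = 0,
                    drift_amplitude = 0, seed = 19)
  g <- generate_session(cfg)
  d <- build_design(g$session)
  sp <- speckled_split(5000, 10, 0.25, seed = 6)
  fit <- fit_baseline(g$session, d, sp, seed = 6)
  lam <- t(g$truth$A_true[, g$truth$cond_index])   # trial x unit expected Hz
  bound <- sapply(1:10, function(i) {
    noise <- mean(lam[, i]) / 0.833                # Poisson rate variance
    stats::var(lam[, i]) / (stats::var(lam[, i]) + noise)
  })
  expect_lt(abs(median(fit$r2_baseline) - median(bound)), 0.05)
})

test_that("rank-1 autoencoder recovers exact and speckled low-rank structure", {
  set.seed(51)
  z_star <- rnorm(300); w_star <- rnorm(25, 1, 0.5)
  Rm <- tcrossprod(z_star, w_star)
  init <- init_autoencoder(Rm)
  expect_gt(abs(cor(init$z0, z_star)), 1 - 1e-10)
  expect_gte(sum(ifelse(init$w0 >= 0, 1, -1)), 0)
  expect_equal(sd(init$z0), 1, tolerance = 1e-8)
  # reconstruction equals the input for exact rank-1 data
  expect_lt(max(abs(tcrossprod(init$z0, init$w0) - Rm)), 1e-6)

  # 25% speckled missingness
  Rm2 <- Rm
  Rm2[matrix(runif(300 * 25) < 0.25, 300, 25)] <- NA
  init2 <- init_autoencoder(Rm2)
  expect_gt(abs(cor(init2$z0, z_star)), 0.99)

  # white noise: reconstruction r2 stays near the random-matrix scale
  noise <- matrix(rnorm(300 * 25), 300, 25)
  init3 <- init_autoencoder(noise)
  recon <- tcrossprod(init3$z0, init3$w0)
  r2 <- 1 - sum((noise - recon)^2) / sum(noise^2)
  expect_lte(r2, 2 / 25 + 0.05)

  # all-missing unit gets a zero loading
  Rm3 <- Rm; Rm3[, 3] <- NA
  expect_equal(init_autoencoder(Rm3)$w0[3], 0)
})

test_that("gain objective gradients match numerical differentiation", {
  set.seed(52)
  nt <- 25; nu <- 3
  cond <- sample.int(36, nt, replace = TRUE)
  S <- matrix(0, nt, 36); S[cbind(1:nt, cond)] <- 1
  Phi <- tent_basis(seq_len(nt))$phi
  R <- matrix(rpois(nt * nu, 5), nt, nu)
  M <- matrix(runif(nt * nu) > 0.3, nt, nu)
  obj <- sharedgain:::make_gain_objective(R, M, cond, S, Phi, 1e-3, 1e-3)
  par <- c(rnorm(nu * 36, 3, 1), rnorm(nu, 0, 0.3), rnorm(nt, 0, 0.8),
           rnorm(nu * 5, 1, 0.5))
  g_num <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (obj$fn(pp) - obj$fn(pm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(obj$gr(par) - g_num)), 1e-5)
})

test_that("the gain model nests the baseline when loadings are zero", {
  g <- generate_session(sim_config(n_units = 8, n_trials = 300, seed = 7))
  d <- build_design(g$session)
  sp <- speckled_split(300, 8, 0.25, seed = 7)
  fit <- fit_baseline(g$session, d, sp, l2_grid = 1e-6)
  R <- fit$rates
  M <- sp$train & !is.na(R)
  obj <- sharedgain:::make_gain_objective(R, M, d$cond_index, d$onehot, d$phi,
                                          0, 0)
  par <- sharedgain:::pack_params(fit$A, numeric(8), rnorm(300), fit$B)
  direct_mse <- mean((fit$prediction[M] - R[M])^2)
  expect_equal(obj$fn(par), direct_mse, tolerance = 1e-8)
})

test_that("the fitted gain model recovers generative latents and loadings", {
  cfg <- sim_config(n_units = 40, n_trials = 600, gain_sd = 1.5,
                    gain_running_coupling = 1, seed = 11)
  g <- generate_session(cfg)
  d <- build_design(g$session)
  sp <- speckled_split(600, 40, 0.25, seed = 111)
  fit <- fit_gain(g$session, d, sp, labels = split_by_running(g$session),
                  seed = 211)
  expect_gte(cor(fit$params$z, g$truth$z_true), 0.8)
  expect_gte(cor(fit$params$w, g$truth$w_true), 0.8)
  # normalization and anchoring conventions
  expect_equal(sd(fit$params$z), 1, tolerance = 1e-8)
  expect_gte(sum(ifelse(fit$params$w >= 0, 1, -1)), 0)
  expect_true(all(fit$result$pop_gain >= 0))
  expect_gt(fit$result$gain_diff_running, 0)
})

test_that("test cells never influence the fitted parameters", {
  g <- generate_session(sim_config(n_units = 12, n_trials = 300, gain_sd = 1,
                                   seed = 15))
  s <- g$session
  d <- build_design(s)
  sp <- speckled_split(300, 12, 0.25, seed = 5)
  fit1 <- fit_gain(s, d, sp, l2_grid = 1e-3, seed = 9)
  s2 <- s
  test_cells <- which(sp$test)
  set.seed(99)
  s2$counts[test_cells] <- sample(s2$counts[test_cells])
  fit2 <- fit_gain(s2, d, sp, l2_grid = 1e-3, seed = 9)
  expect_equal(fit2$params$z, fit1$params$z, tolerance = 1e-10)
  expect_equal(fit2$params$w, fit1$params$w, tolerance = 1e-10)
  expect_equal(fit2$params$A, fit1$params$A, tolerance = 1e-10)
})

test_that("gain statistics follow the identity conventions", {
  params <- structure(list(A = matrix(1, 3, 36), w = c(0.5, 0.2, 0.1),
                           z = rep(0, 50), B = matrix(0, 3, 5)),
                      class = "gain_model_params")
  labels <- list(label = factor(rep(c("running", "stationary"), 25),
                                c("running", "stationary", "ambiguous")))
  res <- gain_statistics(params, list(), labels)
  expect_equal(res$pop_gain, rep(1, 50))
  expect_equal(res$gain_sd, 0)
  expect_equal(res$gain_diff_running, 0)
  # w = 0 forces unit gain no matter the latent
  params$w <- rep(0, 3); params$z <- rnorm(50)
  expect_equal(gain_statistics(params, list(), labels)$pop_gain, rep(1, 50))
  # empty state flagged
  labels0 <- list(label = factor(rep("stationary", 50),
                                 c("running", "stationary", "ambiguous")))
  expect_warning(res0 <- gain_statistics(params, list(), labels0), "empty")
  expect_true(is.na(res0$gain_diff_running))
})
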