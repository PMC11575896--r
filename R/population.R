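#' Leading principal component of population activity
#'
#' Computes the largest eigenvector `u` of the unit x unit covariance of the
#' trial x unit rate matrix and projects the per-unit mean-subtracted rates
#' onto it. Because an eigenvector's sign is arbitrary, `u` is anchored so
#' that the sum of the signs of its entries is non-negative
#' (`u <- u * sign(sum(sign(u)))`, with `sign(0) = +1`): positive values of
#' the projection then correspond to increases in average population firing.
#'
#' @param rates Trial x unit rate matrix (>= 3 trials, >= 2 units). `NA`
#'   entries are tolerated via pairwise-complete covariances but projected
#'   trials must be complete.
#' @return A `population_projection` list: `u` (unit norm), `pc1` (per-trial
#'   projection), `sign_flipped` (whether anchoring flipped the raw
#'   eigenvector).
#' @export
first_neural_pc <- function(rates) {
  X <- as.matrix(rates)
  if (ncol(X) < 2 || nrow(X) < 3) stop("need >= 2 units and >= 3 trials")
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, mu)
  C <- stats::cov(Xc, use = "pairwise.complete.obs")
  if (!all(is.finite(C)) || max(abs(C)) < 1e-12) stop("degenerate covariance")
  u <- eigen(C, symmetric = TRUE)$vectors[, 1]
  flip <- sign0(sum(sign0(u))) < 0
  if (flip) u <- -u
  Xc[is.na(Xc)] <- 0
  structure(list(u = u, pc1 = as.numeric(Xc %*% u), sign_flipped = flip),
            class = "population_projection")
}

#' Correlation with circular-shift permutation significance
#'
#' Pearson correlation between two per-trial series, with a two-sided p-value
#' from a null ensemble of random circular shifts of `y`. Shifting preserves
#' each series' autocorrelation and exact marginal values, so the test stays
#' calibrated when both series are slow (an ordinary Pearson t-test does
#' not). Shifts are drawn at least 10 trials away from 0 (modulo n) so no
#' null draw nearly reproduces the original alignment. The p-value uses the
#' add-one estimator `p = (1 + #(|r_perm| >= |r|)) / (1 + n_perm)`.
#'
#' @param x,y Numeric per-trial series of equal length >= 20.
#' @param n_perm Number of permutations (>= 200).
#' @param seed Integer seed for the shift draws.
#' @param alpha Significance level for the `significant` flag.
#' @return A `session_correlation` list: `r`, `p`, `n_perm`, `significant`.
#' @export
permutation_correlation <- function(x, y, n_perm = 1000, seed = 1L,
                                    alpha = 0.05) {
  stopifnot(length(x) == length(y), n_perm >= 200)
  n <- length(x)
  if (n < 20) stop("need >= 20 trials")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  r <- stats::cor(x, y)
  r_perm <- with_seed(seed, {
    shifts <- sample(10:(n - 10), n_perm, replace = TRUE)
    idx <- outer(seq_len(n) - 1L, shifts, `+`) %% n + 1L
    as.numeric(stats::cor(x, matrix(y[idx], n, n_perm)))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r))) / (1 + n_perm)
  structure(list(r = r, p = p, n_perm = n_perm, significant = p < alpha),
            class = "session_correlation")
}

#' Rank-based comparison of two groups of session statistics
#'
#' Two-sided Mann-Whitney U test between the groups plus a one-sample
#' Wilcoxon signed-rank test of each group's median against zero — the
#' standard pairing for per-session correlation or log-ratio summaries.
#'
#' @param r_a,r_b Numeric vectors (non-empty).
#' @return List with `median_a`, `median_b`, `U` (Mann-Whitney statistic for
#'   the a-over-b orientation), `p` (two-sided), `p_a_vs_0`, `p_b_vs_0`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(r_a, r_b) {
  if (length(r_a) == 0 || length(r_b) == 0) stop("empty group")
  if (length(unique(c(r_a, r_b))) == 1) stop("degenerate input: all values tied")
  mw <- suppressWarnings(stats::wilcox.test(r_a, r_b))
  one_sample_p <- function(v) {
    if (all(v == 0)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
  }
  list(median_a = stats::median(r_a), median_b = stats::median(r_b),
       U = unname(mw$statistic), p = mw$p.value,
       p_a_vs_0 = one_sample_p(r_a), p_b_vs_0 = one_sample_p(r_b),
       n_a = length(r_a), n_b = length(r_b))
}
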