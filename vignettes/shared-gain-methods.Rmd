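---
title: "Methods: shared gain modulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared gain modulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sharedgain)
```

This vignette documents the statistical methods in `sharedgain`, the
assumptions behind them, and the choices made where a published description
leaves the design open. The package analyses trial-structured V1 recordings:
spike counts per (trial, unit), a grating condition per trial (12
orientations × 3 spatial frequencies × 2 drift speeds), mean treadmill speed
per trial, and optional saccade events and pupil size.

## Rates, tuning curves, and the OSI

Counts are taken in a window from 50 ms after grating onset to 50 ms after
offset (absorbing response latency; the window length equals the
833 ms presentation), and divided by the window length to give rates in Hz.

Tuning curves are means in the 12 × 3 orientation × spatial-frequency grid,
pooling drift speeds. Because the animal's behaviour — not the experimenter —
determines how running and stationary trials fall across conditions, the
orientation curve is a weighted average across spatial frequencies, with
weights proportional to the unit's mean response at each spatial frequency
(clipped at zero, normalized to one). Weighting by mean rather than
peak-normalized response is a choice; the two give qualitatively similar
curves for the peaked spatial-frequency profiles this analysis assumes.
Grid cells with no trials are excluded from the weighting rather than
imputed.

The orientation selectivity index is the vector sum on the doubled angle,

$$\mathrm{OSI} = \frac{\sqrt{\left(\sum_k r_k \sin 2\theta_k\right)^2 +
\left(\sum_k r_k \cos 2\theta_k\right)^2}}{\sum_k r_k},$$

with $r$ the baseline-subtracted orientation curve. Two conventions needed
fixing. First, the square root: without it the quantity is dimensionally
inconsistent (numerator in squared rate units over a linear-rate
denominator) and unbounded; with it, the index is the classical circular
measure in $[0, 1]$, equal to 1 for a one-orientation response and 0 for a
flat curve. Second, the baseline: we subtract the minimum of the orientation
curve, which guarantees $r \ge 0$ and hence the $[0,1]$ range. Units with
OSI strictly above 0.2 are called tuned.

## Session and unit inclusion

Sessions enter population analyses when they have more than 250 trials and
a running-trial proportion between 10% and 90% inclusive (both computed
after labelling; see below). Units enter unit-level analyses when recorded
on more than 300 trials with a mean rate above 1 spike/s. For gain-model
summaries, sessions additionally need at least 10 units whose stimulus +
drift model beats a drift-only null on held-out cells — a session where the
stimulus model fits almost nothing cannot constrain a stimulus-scaling
gain.

## Running labels

The labelling criterion is a hysteresis pair of thresholds on mean trial
speed: running at or above 3 cm/s, stationary at or below 1 cm/s, and an
ambiguous dead zone in between excluded from both groups. A single cutoff
would let trials hovering at the threshold flip labels under measurement
noise and dominate small effects; the dead zone costs a few trials instead.
Both thresholds are arguments everywhere they matter.

## First-PC correlation and the circular-shift null

Population activity per session is summarized by projecting per-unit
mean-subtracted rates onto the leading eigenvector of the unit covariance.
The eigenvector's sign is arbitrary, so it is anchored by
$u \leftarrow u \,\mathrm{sign}\!\left(\sum_i \mathrm{sign}(u_i)\right)$
with $\mathrm{sign}(0) = +1$: positive projections then mean elevated
average firing, making the sign of the running correlation interpretable.

Both the projection and running speed are slow signals; a Pearson
correlation between two autocorrelated series has far more variance than
its nominal t-distribution allows, so naive tests reject wildly. The null
here is built from random circular shifts of one series (uniform over
offsets at least 10 trials from zero, modulo the series length), which
preserves each series' autocorrelation and exact values while destroying
their alignment. The two-sided p-value uses the add-one estimator
$p = (1 + \#\{|r_{\mathrm{perm}}| \ge |r|\})/(1 + n_{\mathrm{perm}})$, so
$p > 0$ always. Circular shifting was chosen over Fourier-phase surrogates
as the simplest scheme that keeps marginals exact; the test suite verifies
calibration on AR(1) pairs (false-positive rate within [0.03, 0.08] at
$\alpha = 0.05$ where the naive test exceeds 0.15).

## Unit modulation ratios

Per unit, mean rates over running and stationary trials are compared either
across all stimuli or restricted to the preferred orientation (both drift
directions, all spatial frequencies — conditioning on the single best
orientation × frequency cell is also possible but leaves few trials per
unit). The ratio floors each group mean at 0.1 Hz so near-silent units
cannot produce unbounded ratios; floored units are flagged. Significance
is a percentile bootstrap (default 2000 resamples within each group) of the
difference of means — an interval excluding zero is called a significant
increase or decrease by sign. Aggregation uses the geometric mean
$\exp(\mathrm{mean}(\log \mathrm{ratio}))$, the natural location measure
for a ratio, with a bootstrap-over-units confidence interval; log-ratios
are kept for rank-based cross-group tests.

## The shared-gain model

The model and its fitting are described in `?fit_gain`; the choices that
were genuinely open:

* **Loss.** Mean squared error on rates (Hz), not counts, so unequal window
  lengths are handled; MSE rather than a Poisson likelihood keeps the
  objective identical for the baseline and gain models and matches the
  least-squares character of the rest of the pipeline.
* **Drift basis.** Five piecewise-linear tent functions (order-2 B-splines)
  with knots at the trial-time quantiles {0, 25, 50, 75, 100}%, forming a
  partition of unity. Tents were preferred over order-0 (piecewise
  constant) splines because they produce continuous drift.
* **Speckled holdout.** Cells are held out independently with p = 0.25;
  holding out whole trials would make the per-trial latent unidentifiable
  on held-out trials, while speckling leaves every trial partially
  observed. Held-out cells split 50/50 into validation (early stopping)
  and test (evaluation only). A property test verifies that permuting
  test-cell values leaves every fitted parameter unchanged.
* **Latent treatment.** `z` is a free per-trial parameter (MAP under a
  smoothness penalty), not marginalized — direct optimization of all
  parameters with L-BFGS. The smoothness penalty
  $\lambda_z\,\mathrm{mean}_t (z_{t+1}-z_t)^2$ uses one small coefficient
  ($\lambda_z = 10^{-3}$) for all sessions. Penalties are scaled to *mean*
  squared parameter values so the grid is commensurate with the MSE term
  regardless of population size or session length.
* **Hyperparameters.** The L2 penalty on `A` and `w` is selected from
  {1e-4, 1e-3, 1e-2, 1e-1} using a 20% subset of training cells held out
  for tuning (validation and test cells are never consulted); the baseline
  ridge penalty is selected by 5-fold cross-validation within training
  cells.
* **Initialization.** `A` and `B` come from the baseline fit and the latent
  from a rank-1 autoencoder (alternating least squares on the incomplete
  training-residual matrix, ≤ 100 sweeps, relative tolerance 1e-12). The
  autoencoder's loadings live in residual units — they confound the gain
  loading with each unit's mean stimulus drive — and a naive regression of
  residuals on fitted tuning curves is attenuated because tuning estimates
  co-adapt with the gain on the same trials. The initialization is
  therefore refined before L-BFGS: loadings are re-estimated by a
  within-condition contrast regression using leave-one-out condition means
  (no tuning-curve estimate enters, and no trial contributes to its own
  reference), tuning and drift weights are refit exactly per unit given the
  implied gain, and the latent is re-estimated by per-trial regression;
  two such passes. In the ground-truth recovery tests this refinement is
  what makes loading recovery clear its acceptance bar.
* **Optimization.** L-BFGS with analytic gradients in blocks of 25
  iterations (500 max), ReLU subgradient 0 at the kink, validation MSE
  checked after each block with patience 3; the best-validation iterate is
  kept, and if validation never improves on the initialization the fit
  reverts to it (`reverted_to_init`).
* **Identifiability.** The scaling $z \to cz,\ w \to w/c$ leaves
  predictions unchanged, so after fitting the latent is rescaled to unit
  variance (loadings absorb the scale) and the sign is anchored as for the
  PC. The gain offset of 1 fixes the remaining freedom.
* **Gain statistics.** The reported "population gain" is
  $\bar g(t) = \mathrm{mean}_i\,\mathrm{ReLU}(1 + z(t) w_i)$ — the latent
  projected back to population space and averaged — with its standard
  deviation over trials and its running-minus-stationary mean difference
  (ambiguous trials excluded, Welch t statistic attached). An alternative
  convention (the standard deviation of the scaled latent itself) would
  differ by a loadings-dependent factor; the population-space convention
  was chosen because it is in gain units and comparable across sessions.

## Eye-movement analyses

Saccades are counted in a window from 0.2 s before stimulus onset to 0.1 s
after offset; the per-trial magnitude is the mean over counted saccades
(NaN when none). Pupil size is expressed as a percentage of the
stationary-trial mean. State comparisons use group means with percentile
bootstrap intervals. The saccade-attributable rate change regresses each
unit's trial rate on saccade count plus, optionally, mean magnitude — with
a no-saccade indicator and magnitude 0 on saccade-free trials to keep the
design full rank (if it still is not, the magnitude regressors are dropped
and flagged) — then multiplies coefficients by the running-minus-stationary
difference in mean features and averages over units. Swapping the state
labels negates the estimate exactly; saccade-independent noise moves it
only within sampling error.

## The synthetic-session generator

`generate_session()` draws conditions uniformly over 12 × 3 × 2, presents
each for 0.833 s with a 0.249–0.415 s jittered gap, and emulates:

* **Running:** a two-state Markov chain over trials with mean dwell at
  least 5 trials in each state and stationary occupancy matching
  `run_fraction`; running speeds Gamma-distributed around `run_speed_mean`
  (default 20 cm/s, shape 4), stationary speeds near zero — a bimodal
  speed distribution with bout structure.
* **Tuning:** axial von Mises curves in 2θ with exponentially distributed
  concentration (mean `tuning_concentration` = 1.5), giving a broad OSI
  spread from untuned to sharply tuned; a `ds_fraction` (default 0.3) of
  units get a 1θ direction-selective component; peaked spatial-frequency
  profiles; peak rates uniform on `base_rate_range` (default 2–20 Hz) over
  a 20% untuned pedestal.
* **Latent:** `z` is `gain_running_coupling` × standardized speed plus
  AR(1) noise (φ = 0.8, unit variance), rescaled to `sd(z) = gain_sd`. The
  AR(1) component matters: it makes the latent autocorrelated even apart
  from running, which is exactly the regime the permutation test must
  survive. Coupling +1 makes a mouse-like session, −0.1 a marmoset-like
  one.
* **Loadings:** normal with mean 1, coefficient of variation 0.4, then
  scaled so at most 1% of (trial, unit) gains are clipped by the ReLU.
* **Drift:** an additive baseline `drift_amplitude × peak` per unit
  (default 20% of peak), modulated smoothly on the model's own 5-knot tent
  basis — identifiable by the fitted model by construction. Amplitude 0
  removes the baseline entirely, so condition means converge exactly to
  the tuning weights.
* **Counts:** Poisson with mean rate × duration. With `gain_sd = 0` the
  generator is exactly the baseline (stimulus + drift) model plus noise.
* **Eye signals:** saccades as per-trial Poisson events in the analysis
  window at state-dependent rates (defaults 2.653/2.525 Hz running/
  stationary) with Gamma magnitudes (means 9.261/8.337 deg), and pupil
  size 8% larger during running (`pupil_running_gain` = 1.08) with 5%
  multiplicative noise.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real recordings: non-Poisson dispersion and
unit-specific noise correlations beyond the shared gain; multi-dimensional
or stimulus-dependent modulators; adaptation and within-trial dynamics;
eye-position traces and their retinal consequences (only saccade events);
and the super-sessioning of units across recording days (units are taken
as given; missing unit-trials are represented as NA cells).

Running-speed distributions and several eye parameters are
order-of-magnitude choices exposed in `sim_config`, not measured values.

## Problem sizes and numerical notes

Validation uses sessions of 20–40 units and 300–600 trials (recovery tests
at 40 × 600; convergence tests of condition means and tuning curves at 5000
trials), cohorts of 8–10 sessions per species for the contrast tests, 500
replicates for test-calibration studies, and 500–2000 bootstrap or
permutation resamples — sizes chosen so each property is measured well away
from its decision boundary while the whole suite runs in minutes.
Degenerate inputs are errors, not silent results: zero-variance series in
the permutation test, constant rate matrices in the PC (singular
covariance), empty state groups in comparisons, non-positive durations, and
all-tied groups in rank tests. Seeds thread explicitly through every
stochastic function, and pipeline stages derive their seeds from a master
seed and stage name, so any result is reproducible from its configuration.

## Known limitations

The latent is one-dimensional by design; sessions dominated by richer
shared structure will load it with a mixture. MSE fitting underweights
high-rate units' Poisson noise relative to a likelihood fit. The
geometric-mean ratio floors silent units, biasing ratios toward 1 for very
sparse populations. The permutation null assumes approximate stationarity
within a session — abrupt regime changes (e.g., a single long running bout
covering half the session) reduce the effective number of distinguishable
shifts. And parameter recovery degrades gracefully but measurably as
`gain_sd` shrinks: with little gain variance there is little signal to
recover.
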