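---
title: "Stochastic SIR inference for tree-pest removal counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic SIR inference for tree-pest removal counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Control programmes for the oak processionary moth (OPM) remove nests from
infested oak trees and record, each year, the cumulative number of unique
trees that have ever had nests removed. `opmsir` treats such a series as
partial, noisy observation of a closed-population epidemic among trees and
infers the infestation dynamics from it: the removal rate, how variable the
infestation pressure has been from year to year, the observation noise, the
latent numbers of susceptible and infested trees, and a yearly basic
reproduction number on which control decisions can be based.

## Model

A fixed population of `N` trees is split into susceptible (`S`), infested
(`I`) and removed (`R = N - S - I`) compartments, with pseudo-reactions

* infestation: `S + I -> 2I` at hazard `exp(beta_log) * S * I`,
* removal: `I -> R` at hazard `gamma * I`.

The per-pair infestation rate is stored on the log scale, `beta_log(t)`,
and evolves as a driftless Brownian motion with volatility `sigma`
(1/sqrt(year)), which absorbs unmodelled year-to-year changes in
infestation pressure (weather, spraying effort, dispersal). Positivity of
the rate is automatic; the rate is only exponentiated where a hazard is
evaluated. The latent state is `X_t = (S_t, I_t, beta_log_t)`, described by
an Ito diffusion whose drift and diffusion matrix (`sir_drift()`,
`sir_diffusion()`) come from the chemical-Langevin treatment of the two
reactions. The exact integer-valued Markov jump process formulation lives
only in the synthetic-data simulator (`simulate_mjp()`); inference uses the
continuous relaxation throughout.

Observations are yearly cumulative removal counts `R(t)`. Since `N` is
fixed, observing `R(t)` is equivalent to observing `y_t = N - R(t) =
S_t + I_t`, and the package converts once to `y` on input. The observation
model is Gaussian with mean-proportional variance,
`Y_t ~ N(P'x_t, sigma_e^2 * P'x_t)` with `P = (1, 1, 0)'`: a Gaussian
approximation to Poisson counting noise in which `sigma_e` decouples the
variance from the mean. The observation variance is evaluated at the
predicted mean and floored at one tree so it cannot vanish as the epidemic
exhausts the susceptible pool.

### Linear noise approximation

The nonlinear diffusion has no tractable transition density. The linear
noise approximation (LNA) replaces it by a Gaussian: the mean `eta_t`
follows the deterministic rate ODE `d eta/dt = a(eta, theta)`, and the
covariance follows `dV/dt = H V + V H' + b(eta)`, with `H` the drift
Jacobian (`sir_jacobian()`) evaluated along the mean path. Both are
integrated jointly (3 mean + 6 unique covariance entries, plus 9 entries of
the fundamental matrix `G` when latent-path sampling needs it) by an
adaptive Dormand-Prince Runge-Kutta 4(5) pair (`deSolve`, rtol `1e-8`,
atol `1e-10`); the right-hand side is compiled C for speed. Because the
observation is a *linear* function of the state, combining the LNA with the
Gaussian observation model gives a closed-form Kalman-style forward filter
(`lna_filter()`) whose accumulated one-step predictive densities are the
marginal likelihood `log pi(y | theta)`.

Design choices in the filter, and why:

* **Restarting.** After each observation update the next interval's moment
  ODEs start from the filtered mean and covariance, keeping the
  linearisation local to the data-supported region. A non-restarting
  variant (one unbroken mean path, filtered moments carried through the
  fundamental matrix) is available via `lna_control(restart = FALSE)`;
  neither dominates on difficult data, and restarting is the standard
  companion of this likelihood method.
* **Initial-rate marginalisation.** The Gaussian prior
  `beta_log_0 ~ N(-8.5, 0.5^2)` is conjugate under the LNA, so it enters
  the filter as initial covariance `V_0 = diag(0, 0, 0.25)` and is
  marginalised analytically; the MCMC stays 3-dimensional. A switch
  (`mcmc_control(sample_beta_log0 = TRUE)`) re-exposes it as a fourth
  sampled parameter for sensitivity analysis.
* **First observation.** The time-0 observation contributes a likelihood
  term by default (`lna_control(include_first_obs = FALSE)` drops it).
* **Negative-mean handling.** Filtered means of `S` or `I` may make small
  negative excursions near the state boundary — that is ordinary slack of a
  Gaussian approximation to a positive process, and particle-filter
  cross-checks show the likelihood remains informative there. Only gross
  breakdown (an excursion beyond 10% of `N`) is treated as a failed
  linearisation and rejected with a `-Inf` log-likelihood; the threshold is
  configurable (`lna_control(neg_tol = )`) for users who want stricter
  vetoes.

### Where the approximation strains

The LNA linearises the response of the epidemic to `beta_log` along the
mean. Over a one-year inter-observation gap the filtered uncertainty in
`beta_log` is roughly `sigma` (about 0.75 under the default study
conditions), so the hazards span a factor of `exp(2 * 0.75)` across the
state distribution while the filter uses a single tangent. Monte-Carlo
moment checks on hard synthetic data sets show the consequences: the true
one-year predictive of `S + I` can be strongly left-skewed with roughly
double the LNA's variance, so a low count pushes the linear Kalman update
to overshoot `beta_log` upward, after which the mean ODE can explode and
the remaining likelihood terms collapse. The result is a likelihood
surface with spurious structure of hundreds of nats on epidemics whose
latent rate wandered substantially, while a bootstrap particle filter shows
the exact surface is nearly flat there. Two practical consequences, both
visible in the package's own acceptance tests: the LNA marginal likelihood
can sit several nats below a particle-filter estimate on such data, and
posterior intervals for `sigma` can concentrate falsely, so simulation
studies at volatile settings under-cover `sigma`. On gently varying data —
which includes series resembling the real park records — the filter is
essentially exact (it matches particle-filter estimates to well under the
Monte-Carlo error in benign regimes, and to about one nat at
`sigma = 0.1`).

## Priors and MCMC

Defaults follow the study configuration: `gamma ~ LN(0, 0.5^2)` (median
removal time one year, 95% interval 0.38-2.66 years), `sigma ~ LN(1, 1)`,
`sigma_e ~ LN(1, 1)`, and `beta_log_0 ~ N(-8.5, 0.5^2)`; with `N = 5000`
these imply a 95% prior interval for `R0 = exp(beta_log_0) N / gamma` of
(0.25, 4.1) (`prior_r0_interval()`).

`fit_mcmc()` runs random-walk Metropolis on
`(log gamma, log sigma, log sigma_e)` — on that scale the lognormal priors
are exactly Gaussian, so no separate Jacobian bookkeeping is needed — with
a joint Gaussian proposal (initial sd 0.1) whose global scale is adapted
toward 30% acceptance during burn-in only. Defaults are 10000 iterations
with 2000 burn-in, matching the study's run length. If the starting value
lands in a rejected region the sampler searches the prior for a valid
start. Given the retained draws, latent paths are sampled for a thinned
subset (every 10th draw by default) by forward-filter backward-sampling
over the Gaussian filter states, with optional Gaussian bridge
interpolation inside each yearly interval; each stored path is paired with
its own parameter draw, so transformed summaries preserve the joint
posterior dependence.

Prior-only mode (`mcmc_control(likelihood = FALSE)`) targets the prior
itself and is the package's calibration gate: the sampled quantiles of
`1/gamma` and of prior `R0` must reproduce the closed forms above within
Monte-Carlo error, which the test suite checks with effective-sample-size
based error bands. `chain_diagnostics()` reports Geyer-style ESS,
split-R-hat and the acceptance rate.

## Prediction and R0

Within-sample predictive bands replay the observation model over stored
`(theta, x)` draws. Out-of-sample predictions push each stored terminal
latent state forward through the stochastic differential equation itself
(Euler-Maruyama, step 1/100 year) rather than through the LNA Gaussian, so
predictive skew and positivity are respected; the LNA push-forward is not
used for forecasting. Reaction increments are truncated at zero within
each Euler step, which keeps the latent cumulative removal count monotone
and confines it to `[0, N]` — forecasts saturate as the susceptible pool
depletes. Forward summaries report the latent `R(t) = N - S - I` by
default; observation noise is added only when mimicking the observable
predictive (`observation_noise = TRUE`, the default for the one-step-ahead
check against a held-out year). The yearly reproduction number is the
deterministic transform `R0(t) = exp(beta_log_t) N / gamma` applied
draw-by-draw (`r0_posterior()`).

## Synthetic data

`simulate_mjp()` is an exact Gillespie sampler of the integer-valued
process; because Gillespie's algorithm needs locally constant hazards, the
Brownian log rate is frozen on a fine grid (default 1/100 year) and
receives exact `N(0, sigma^2 * step)` increments at the nodes.
`simulate_sde()` is an Euler-Maruyama scheme (default step 1/365 year) in
per-reaction form — Gaussian reaction counts truncated at zero — which
reproduces the diffusion's drift and covariance while keeping removals
cumulative; negative state excursions are truncated to zero rather than
rejected, to avoid biasing rare near-extinction paths. `observe()` applies
the observation model, rounds the reported counts to whole trees and clips
them to `[0, N]`, while keeping the raw real-valued observation alongside
(the filter consumes the raw value). One integer seed fully determines a
fixture.

`generate_fixture()` encodes the two study-scale presets: `"bushy-like"`
(`N = 5e3`, `beta_log_0 = -8`, `gamma = 1`, `sigma = 0.75`,
`sigma_e = 1`) and `"richmond-like"` (`N = 4e4`, `beta_log_0 = -10`,
`gamma = 1`, `sigma = 0.5`, `sigma_e = 0.5`), eight yearly observations
each. The initial infested fractions (100 of 5000; 1400 of 40000) mirror
the reported first-year removal increments; the richmond-like population
size is the value at which the preset's rate reproduces the reported
whole-population rate `beta * N` of about 1.8. What these fixtures do not
emulate: spatial structure and dispersal, per-tree nest counts,
re-infestation, and any systematic drift in control effort. Passing
recovery tests on them therefore demonstrates that the inference machinery
is consistent with its own model assumptions at park scale — not that the
model is a complete description of real OPM spread. Note also that drawing
fresh Brownian rate paths at `sigma = 0.75` regularly produces epidemics
far more violent than the smooth historical series, which is exactly the
regime where the LNA strains (above).

## Numerical choices and problem sizes

Tolerances: ODE rtol `1e-8` / atol `1e-10`; covariances are re-symmetrised
each step and must pass an eigenvalue check at `-1e-8`; backward-sampling
solves use a scale-aware ridge (`1e-9` of the covariance scale) with an
eigenvalue pseudo-inverse fallback; the observation variance is floored at
one tree. Monte-Carlo problem sizes used by the test suite — chosen as
desk-scale defaults — are 1e5 Gillespie replicates for moment validation,
1e5-particle bootstrap particle filters (5 replicates) for the likelihood
oracle, 10 replicate fits of 2000 iterations for parameter recovery, and
20 replicate fits for one-step predictive coverage (19/20 held-out years
covered in the packaged study).

## Known limitations

* The LNA likelihood degrades on data generated with large `sigma`
  (volatile latent rates), as analysed above; `sigma`'s posterior should
  be interpreted cautiously on such series.
* The one-year observation spacing is structural: the filter would be
  markedly more accurate with sub-annual counts.
* Forecasts condition on the fitted control regime; the model has no
  mechanism for changes in management effort.
* The model ignores spatial structure and treats removed trees as immune
  on the study timescale (no SIRS re-infestation).
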