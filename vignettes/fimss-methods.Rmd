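---
title: "Interval-wise LNA Fisher information for stochastic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-wise LNA Fisher information for stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell time courses of signaling pathways are intrinsically stochastic:
molecule numbers are small, fluctuations carry information, and the observed
dynamics can differ qualitatively from the deterministic rate equations (the
built-in Calcium oscillation model is the canonical example — bursting
oscillations from 0 to ~10\,000 molecules within a few time units, where the
ODE solution shows only small regular oscillations). Experimental design asks,
*before* any experiment is run: at which time points, and for which observable
species, should one measure to estimate the kinetic parameters as precisely as
possible?

The standard design currency is the Fisher information matrix
$FI(T, \vartheta)_{ij} = \mathbb{E}_O\!\left[\partial_{\vartheta_i} \log L(O,\vartheta)\,
\partial_{\vartheta_j} \log L(O,\vartheta)\right]$,
whose inverse is the asymptotic covariance of the maximum-likelihood
estimator. For Markov jump processes the likelihood $L$ is intractable in all
but toy models, so this package approximates both ingredients: the likelihood
by an interval-wise linear noise approximation with state estimation (the MSS
objective), and the expectation by a Monte-Carlo mean over pseudo datasets.

## Model and objective

A reaction network is a stoichiometric matrix $S \in \mathbb{Z}^{D\times r}$
with propensities $v_j(x,\theta)$ in particle-number units
(`reaction_network()` stores them as expression trees so the species Jacobian
can be formed symbolically). Between two measurements separated by
$\Delta t$, the transition density is approximated as Gaussian with

* mean $x(\Delta t)$ from $\dot x = S\,v(x,\theta)$, and
* covariance from the LNA ODE
  $\dot\Sigma = J\Sigma + \Sigma J' + \Omega^{-1} D$, $\Sigma(0)=0$, with
  $J = S\,\partial v/\partial x$ and $D_{ik} = \sum_j S_{ij}S_{kj}v_j$.

Crucially, the LNA is restarted on **every interval** from the current state
estimate, so it only needs to hold over one inter-sample distance — far less
restrictive than a Gaussian approximation over the whole horizon. With
observations $O_i$ of the observed components (Gaussian measurement noise
$\Sigma^{meas}$, possibly zero), each interval contributes the closed-form
Gaussian convolution

$$\log f\!\left(O_i \,\middle|\, P\,x(\Delta_i;\theta,\hat\nu_{i-1}),\;
P\,\Sigma(\Delta_i;\theta,\hat\nu_{i-1})\,P' + \Sigma^{meas}\right),$$

and the state estimate is advanced to the joint mode of prediction ×
measurement (`state_update()`): on observed components the precision-weighted
combination, on unobserved components the conditional mode. The sum over
intervals is the MSS objective `mss_loglik()`. The interval integral is always
evaluated in this closed form; numerical quadrature exists only as a test
oracle.

Two readings of the interval covariance appear in the source literature
($\Sigma(\Delta t;\theta,\nu_{i-1})$ vs $\Sigma(\Delta_i;\theta)$); this
package adopts the start-state-dependent one, i.e. the covariance ODE is
re-integrated along the mean started at $\hat\nu_{i-1}$ for every interval.

### Outlier guard and state floor

A poor state estimate in a sparsely observed nonlinear system can make one
transition astronomically unlikely and let a single interval dominate the
Fisher matrix. An interval is therefore *masked* when any observed
component's standardized residual exceeds the $10^{-15}$ standard-normal
quantile ($|z| > 7.94$): its log-density and gradient contributions are
dropped, but state updating still runs so later intervals stay anchored.
State-estimate components are floored at 0.1 for numerical reasons. The same
floor is applied to the *propagation anchor* during pseudo-data generation:
a trajectory that grazes the state-space boundary can draw a slightly
negative (unrounded) state, and propagating the LNA from a negative state
gives negative propensities and an indefinite diffusion. The drawn data
values themselves are never clamped — the Gaussian has full support.

## The three Fisher matrices

**`fi_mss()`** — the package's main quantity:
$FI_{MSS} = \frac1M \sum_{k=1}^M g_k g_k'$ with
$g_k = \nabla_\vartheta F_{MSS}(O^{(k)}, \vartheta)$. The $M$ pseudo datasets
are drawn from the same interval-wise Gaussians the objective uses
(`lna_pseudo_data()`, rounding off so states depend smoothly on $\theta$),
which keeps the information estimate internally consistent — and makes it
deterministic given the master seed, so design optimizers can treat it as a
smooth objective. Gradients are central finite differences (relative step
$10^{-4}$, floor $10^{-6}$) with the pseudo data and the interval masks
frozen at the evaluation point. The free-parameter vector $\vartheta$
contains the kinetic parameters, the unobserved initial-state components and
any free measurement variances; printed comparisons for kinetic parameters
use the marginal sub-block of $FI^{-1}$.

**`fi_benchmark()`** — the full-horizon reference: the stacked trajectory is
modeled as one multivariate normal with mean the ODE solution and blockwise
covariance $\Sigma_B$ built from $\Sigma(t_i)$ and the fundamental matrix,
$\mathrm{cov}(\nu_s,\nu_t) = \Sigma(s)\Phi(s,t)'$. The Fisher matrix is the
standard Gaussian-family expression
$\partial_j\mu' \Sigma_B^{-1} \partial_k\mu + \tfrac12 \mathrm{tr}(\Sigma_B^{-1}
\partial_j\Sigma_B\, \Sigma_B^{-1} \partial_k\Sigma_B)$. The initial time
carries the known initial condition and zero variance, so the stacked model
runs over the $n$ measurement times only (including $t_0$ would make
$\Sigma_B$ singular). $\Phi$ is accumulated from per-interval factors
$\Phi(t_{i-1},t_i)$ obtained in the same forward pass as the mean and
covariance; this is algebraically identical to integrating $\Phi(s,t)$ per
pair but stays well scaled when $\Phi(t_0,t)$ decays below double precision
over long horizons (100 observations at $\Delta t = 15$ reach $t=1500$,
where $e^{-\theta_2 t}$ underflows).

**`fi_exact_id()`** — for the Immigration-Death model only, the exact CME
transition law is available in closed form: survivors are thinned
binomially, immigrants arrive Poisson,
$\nu_{t+\Delta t} \sim \mathrm{Bin}(\nu_t, e^{-\theta_2\Delta t}) +
\mathrm{Pois}\!\left(\tfrac{\theta_1}{\theta_2}(1-e^{-\theta_2\Delta t})\right)$.
(The package validates this form against a matrix exponential of the CME
generator in its test suite.) The Fisher matrix is the double sum of
log-derivative products over successive states, weighted by the transition
probability and the marginal state distribution, truncated at state 30 by
default. The truncation check is the largest per-interval, marginal-weighted
probability leak (threshold $10^{-6}$); an accumulated-leak criterion would
reject the study's own truncation-30 setting over 100 intervals even though
the induced error is negligible.

## Design criteria and optimization

`summarize_fi()` maps a Fisher matrix to the D-criterion (determinant,
confidence-ellipsoid volume), E-criterion (minimum eigenvalue, largest
axis), the estimator correlation matrix from $FI^{-1}$, and the predicted
relative error $100\sqrt{(FI^{-1})_{ii}}/\theta_i$ in percent. The square
root is deliberate: only with it does the prediction carry the units of the
empirical ARSE $100\sqrt{\frac1N\sum(\hat\theta_i-\theta_i)^2/\theta_i^2}$.

`scan_designs()` evaluates a criterion over equidistant designs (re-using
one master seed across designs so Monte-Carlo noise does not blur the
comparison). `optimize_design_pso()` searches non-equidistant schedules with
a particle swarm over *inter-sample distances* (ordering holds by
construction) within spacing bounds, default $[1, 12]$; candidate times can
be restricted to integers (ties round down, duplicates repaired upward).
Default budget: 20 iterations, 25 particles, $M = 500$; the remaining PSO
hyperparameters (inertia 0.7, cognitive/social 1.5, reflecting bounds) are
fixed conventional choices.

## Diagnostics: when does the approximation hold?

* `whitened_residual_ks()` — if the full-horizon Gaussian model is right,
  $A(\nu - \mu)$ with $(A'A)^{-1} = \Sigma_B$ is i.i.d. standard normal;
  likewise interval-wise with the interval LNA moments. A two-sided KS test
  against the standard normal, applied to exact-simulation trajectories at
  the true parameters, shows the benchmark assumption failing with growing
  horizon on the Lotka-Volterra model while the interval-wise assumption
  survives.
* `halfstep_fi_check()` — inserts midpoints into the design and compares the
  diagonals of $FI_{MSS}$ before and after (same seed). If the interval-wise
  LNA holds, halving the step cannot change the information content, so the
  ratios sit near 1; on the Calcium model at $\Delta t \ge 1$ they collapse
  by orders of magnitude, flagging the breakdown. The report gives mean and
  SD of the ratios (1 SD; double it for a 2-SD band).

## Estimation and empirical validation

`estimate_parameters()` maximizes any of the three objectives with a
bounded derivative-free search (Nelder-Mead on log-parameters, soft box
penalty, 5 multi-starts by default — the source study does not publish its
optimizer settings, so these are deliberately plain and configurable).
`simulation_study()` repeats simulate-then-estimate and
`empirical_fi_from_estimates()` inverts the sample covariance of the
estimates ($FI_{emp}$), after removing non-converged replicates (the
Immigration-Death rule: $\hat\theta_1 > 3$), and reports empirical ARSEs.

## Built-in models and study conditions

| model | $\theta^{(0)}$ | $\nu_0$ | role |
|---|---|---|---|
| `immigration_death` | $(1, 0.1)$ | $10$ | exact reference; LNA is exact in mean and variance |
| `lotka_volterra` | $(0.5, 0.0025, 0.3)$ | $(71, 79)$ | oscillations; partial observation (LV4: prey only) |
| `calcium` | 12 parameters, Eq.-wise split into 8 unit-stoichiometry reactions | $(10,10,10)$ | bursting, highly nonlinear; LNA validity limit |

The Calcium ODE terms are mapped one-to-one onto reactions; this term-wise
decomposition is the conventional stochastic reading of the model but is not
unique — any split with the same net rates shares the mean dynamics while
the diffusion depends on the decomposition. All models use particle-number
propensities with $\Omega = 1$; the volume is kept explicit so the
$\Omega^{-1}D$ term stays honest for other models.

The measurement-noise covariances used in the original Immigration-Death and
Lotka-Volterra studies are not published; this package adopts
$\Sigma^{meas} = 0$ for them, which also makes the state update collapse to
the data on observed components. Designs count "$n$ observations" as $n$
intervals after the known initial state at $t_0$ (the initial point is not a
measurement).

## Numerical choices

* Stiff-capable `lsoda` with `rtol = 1e-8`, `atol = 1e-10` (the Calcium
  model spans four orders of magnitude in a few time units); tolerances are
  arguments everywhere.
* Only the upper triangle of $\Sigma$ is integrated; results are symmetrized
  and eigenvalues in $[-10^{-10}\lambda_{max}, 0)$ clamped to zero ("PSD
  repair"). Matrix square roots are upper-triangular Cholesky factors
  throughout (pseudo-data, whitening), chosen for determinism; any factor
  with $A'A = \Sigma$ would be statistically equivalent.
* The Monte-Carlo ensemble is propagated jointly: all $M$ interval systems
  are stacked into one ODE solve with a vectorized right-hand side, chunked
  so the solver workspace stays bounded. Ensemble members are coupled only
  through shared adaptive step control (differences at solver tolerance).
* Reproducibility: trajectory $k$ draws from L'Ecuyer-CMRG substream $k$ of
  the master seed, so enlarging $M$ extends the ensemble without reshuffling
  earlier trajectories.
* Monte-Carlo problem sizes in the package's own checks: $M = 1000$ for the
  Immigration-Death correlation tables, $M = 200\ldots300$ for
  Lotka-Volterra (matching the study's observation that a few hundred
  pseudo datasets already stabilize the entries — the per-entry standard
  error shrinks as $M^{-1/2}$ and is reported in the matrix metadata).
  The Calcium half-step diagnostic is exercised on a 20-interval horizon
  with $M = 16$ and two representative free parameters: each stiff
  ensemble interval-solve costs on the order of a second, and the
  diagnostic probes a ratio, not a precise value.

## What the synthetic data does and does not show

All validation runs on data the package generates itself: exact Gillespie
simulation (`gillespie_simulate()`) for ground-truth trajectories, and the
LNA scheme for pseudo data. These capture demographic (intrinsic) noise
exactly (SSA) or to second moments (LNA), but contain none of the features
of real single-cell measurements: extrinsic cell-to-cell variability,
non-Gaussian measurement error, uneven sampling jitter, or model
misspecification. Passing tests therefore demonstrate internal consistency
of the approximation chain and correct reproduction of the study's
quantities — not that the MSS Fisher matrix is accurate for any particular
laboratory system. The diagnostics section is the tool to ask that question
for a concrete model and design.

## Known limitations

* The Fisher matrix is an asymptotic, quadratic measure; strong nonlinear
  non-identifiabilities are invisible to it (profile-likelihood methods are
  the usual complement).
* $FI_{MSS}$ inherits the interval-wise LNA: for inter-sample distances
  where the half-step check fails, its values are not trustworthy — that is
  precisely what the check is for.
* The exact Fisher matrix exists only for the Immigration-Death process;
  for other models validation is relative (benchmark, empirical).
* Gradients are finite differences; adjoint or symbolic derivatives would
  cut the cost for large parameter spaces.
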