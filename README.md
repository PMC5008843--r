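# fimss

Fisher-information experimental design for intrinsically stochastic
reaction networks.

## Why

Single-cell time courses in systems biology — gene expression, predator-prey
style oscillators, bursting Calcium signaling — are driven by small molecule
numbers: the fluctuations are part of the signal, and the dynamics can differ
qualitatively from the deterministic rate equations. Choosing *when* to
measure, and *which* species, decides how precisely the kinetic parameters
can ever be estimated. The Fisher information matrix
`FI(T, ϑ)ᵢⱼ = E[∂ᵢ log L · ∂ⱼ log L]` is the standard currency for that
decision: its inverse is the asymptotic covariance of the maximum-likelihood
estimator, so designs can be ranked — before any experiment — by its
determinant (D-criterion, confidence-ellipsoid volume) or minimum eigenvalue
(E-criterion, worst axis).

For Markov jump processes the likelihood is intractable, so `fimss`
approximates it with an interval-wise linear noise approximation (LNA) plus
multiple-shooting state estimation (the **MSS objective**): each
inter-measurement interval gets its own Gaussian transition density, started
at the current state estimate with zero initial covariance, so the LNA only
has to hold between consecutive measurements — not over the whole horizon.
The Fisher matrix is then the Monte-Carlo mean of score outer products over
`M` pseudo datasets drawn from the same interval-wise Gaussians:

```
FI_MSS(T, ϑ) = (1/M) Σₖ ∇F_MSS(O⁽ᵏ⁾, ϑ) ∇F_MSS(O⁽ᵏ⁾, ϑ)'
```

Two reference constructions ship alongside, for validation: the
**benchmark** Fisher matrix of a single multivariate normal over the whole
stacked trajectory (ODE mean, full-horizon LNA covariance with
inter-temporal blocks `Σ(s)Φ(s,t)'`), and the **exact** Fisher matrix of the
Immigration-Death process from its closed-form chemical-master-equation
transition law (binomial survival ⊛ Poisson immigration).

Three study models are built in: Immigration-Death (`θ = (1, 0.1)`,
`x₀ = 10`), Lotka-Volterra (`θ = (0.5, 0.0025, 0.3)`, `ν₀ = (71, 79)`), and
a 12-parameter bursting Calcium oscillation model (G-protein / PLC / Ca).

## Worked example

How strongly are the two Immigration-Death parameters entangled at an
inter-sample distance of 1, and is the Monte-Carlo approximation to be
trusted? Compare all three constructions on the same design:

```r
library(fimss)

m  <- builtin_model("immigration_death")
d  <- equidistant_design(n = 100, dt = 1)      # 100 observations after t0

fi_mc <- fi_mss(m$network, m$param, d, M = 1000, seed = 1)
fi_bn <- fi_benchmark(m$network, m$param$theta, nu0 = 10, d)
fi_ex <- fi_exact_id(m$param$theta, d, truncation = 30, nu0 = 10)

sapply(list(mss = fi_mc, benchmark = fi_bn, exact = fi_ex),
       function(fi) summarize_fi(fi, theta_true = m$param$theta)$correlation[1, 2])
#>       mss benchmark     exact
#> 0.6584257 0.7276076 0.6678325
```

All three agree that at `Δt = 1` the estimators of immigration and death
rate are strongly positively correlated (~0.63–0.73): the steady state pins
down only their ratio, and one unit of spacing resolves the fluctuation
information that separates them only partially. Shorter spacings decorrelate
the estimates (exact: 0.45 at `Δt = 0.5`); longer spacings approach complete
confounding (0.99 at `Δt = 15`). The predicted per-parameter error comes
from the same summary:

```r
summarize_fi(fi_ex, theta_true = m$param$theta)$predicted_arse
#>   theta1   theta2
#> 17.36052 17.35573        # percent
```

Design scans and non-equidistant optimization follow the same pattern:

```r
scan_designs(m$network, m$param, dts = c(0.5, 1, 2, 5), n_points = 100,
             criterion = "E", fi_method = "exact_id")
opt <- optimize_design_pso(m$network, m$param, n_points = 10,
                           spacing_bounds = c(1, 12), criterion = "D",
                           fi_method = "mss", M = 500, seed = 1)
```

A thin command-line wrapper is installed at `inst/scripts/fimss`
(`simulate`, `fi`, `design-scan`, `design-optimize`, `estimate`,
`diagnose`, `reproduce --table {1,2,3,4,5,6,8}`, ...).

## Validity diagnostics

`halfstep_fi_check()` inserts midpoints into a design and compares Fisher
diagonals — ratios near 1 mean the interval-wise LNA holds (Immigration-
Death, Lotka-Volterra at all tested spacings), ratios orders of magnitude
below 1 flag breakdown (the Calcium model at `Δt ≥ 1`).
`whitened_residual_ks()` tests the Gaussian assumption itself on simulated
trajectories, full-horizon vs interval-wise.

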