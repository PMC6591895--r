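---
title: "Movement and location-error variances as linear functions of covariates"
author: "bbcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement and location-error variances as linear functions of covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbcm)
```

## The model

A track is a sequence of $n+1$ planar locations $Z_0,\dots,Z_n$ observed at
strictly increasing times $t_0 < \dots < t_n$ with lags
$\tau_i = t_{i+1} - t_i$. The animal's true path is planar Brownian motion
whose diffusion rate may change from segment to segment: over segment $i$
each coordinate axis diffuses with variance $\sigma_i^2 \tau_i$
(units $m^2/s$ for $\sigma_i^2$). Each observed location carries
independent isotropic Gaussian measurement error with per-location
variance $\delta_i^2$ ($m^2$).

The data entering the likelihood are the increments
$X_i = Z_i - Z_{i-1}$. Because consecutive increments share the
measurement error of their common location, the increment vector per axis
is zero-mean Gaussian with a **symmetric tridiagonal** covariance:
diagonal $\sigma_i^2\tau_i + \delta_i^2 + \delta_{i+1}^2$, off-diagonal
$-\delta_{i+1}^2$. With constant $\sigma^2$ and $\delta^2$ this collapses
to the classical homoscedastic form ($\sigma^2\tau_i + 2\delta^2$,
$-\delta^2$). The two axes are independent and share one covariance
(isotropic model), so a single factorization serves both.

The distinguishing feature of the model is that both variance vectors are
**linear in covariates** through ordinary design matrices:
$$\sigma^2 = M_\sigma\,\beta_{\sigma^2}, \qquad
  \delta^2 = M_\delta\,\beta_{\delta^2},$$
with $M_\sigma$ built from per-segment covariates ($n$ rows — a segment's
covariates describe the whole interval, not its endpoints) and $M_\delta$
from per-location covariates ($n+1$ rows). Variances, not standard
deviations, are modelled because variances add.

### Estimating the origin

Treating the start of the track as known is rarely justified: the first
fix carries the same error as every other fix. The likelihood is therefore
extended (by default) with the deviation $Z_0 - \gamma$ of the first
observed location from the unknown origin $\gamma$: it has variance
$\delta_1^2$ and covariance $-\delta_1^2$ with the first increment, so the
extended covariance is again tridiagonal and evaluation stays $O(n)$.
Origin estimation matters for placing the utilization distribution in
space; the variance coefficients themselves are driven by the distances
between locations, and a fixed-origin mode (`estimateOrigin = FALSE`)
reproduces the increments-only formulation.

### Evaluation

The exact log-likelihood is computed from the $LDL^\top$ factorization of
the tridiagonal bands (no square roots, no dense matrix), implemented in
C++. The pivots double as a positive-definiteness check: any non-positive
pivot — or any non-positive generated variance — makes the parameter
vector infeasible and the log-likelihood $-\infty$, which optimizers and
samplers reject naturally. Positivity is enforced by this rejection rather
than by reparameterization (e.g. log-links) so that coefficients stay on
the interpretable variance scale and treatment contrasts read directly as
variance differences. When the design has a strictly signed leading
column, `interceptFeasibleBound()` gives the exact feasibility bound of
the leading coefficient given the others.

## Covariates

Terms are declared per side with `interceptTerm()`, `linearTerm()`,
`factorTerm()` and `splineTerm()`; `buildDesign()` expands them against a
trajectory's covariate tables.

* **Factors** use treatment contrasts: the baseline level is absorbed by
  the intercept, other levels get indicator columns. Factor columns use
  their declared level order (first level = baseline); plain character
  columns fall back to first-appearance order with a lexicographic
  tie-break, which is deterministic for any input.
* **Continuous covariates** may be centred/scaled internally
  (`scaleColumns()`) for optimizer conditioning. The transform record
  makes the coefficient back-transformation exact, and all reported
  estimates are on the original covariate scale. Columns are centred only
  when the side has an intercept to absorb the shift. Spline columns are
  never scaled — they are already bounded in $[0,1]$ and scaling would
  destroy the partition of unity that makes the basis interpretable.

### Circular daily splines

Periodic activity patterns (the daily cycle, by default
$P = 86400\,$s) enter as cubic B-splines on a circle, so the curve wraps
midnight without an artificial cut. With $K$ distinct knots the basis has
exactly $K$ functions, non-negative and summing to one at every phase.
Knots may be placed non-uniformly: when a tag only records during the day,
knots belong where the data are, since nothing constrains the curve
overnight.

Because $\sigma_i^2$ represents a whole segment, movement-side spline
columns are **segment averages**
$\frac{1}{\tau_i}\int_{t_i}^{t_{i+1}} B_j(t \bmod P)\,dt$, while
error-side spline columns are instantaneous values at each fix. The
integral is computed by splitting the interval at knots and applying
21-node Gauss–Legendre quadrature per span — exact for a piecewise cubic
up to round-off, deterministic, and with whole periods reduced
analytically ($\int_0^P B_j$ is computed once). A full circular basis
contains the constant, so combining it with a free intercept would leave
the model with multiple solutions; `designSpec()` rejects that
combination unless the spline is declared with
`separateConstant = TRUE`, which re-expresses the basis as $K-1$ centred
differences.

### Window-restricted interactions

`duplicateSplineColumns()` implements an interaction between the daily
pattern and a segment-level factor restricted to a time window (e.g.
"different late-morning activity on hot days"): basis functions whose
peak — argmax on a one-minute grid of the period — falls inside the
window are duplicated; copies are multiplied by the 0/1 segment
indicator, originals by its complement. The two regimes then have
independent coefficients in the window and shared coefficients elsewhere.
Argmax (rather than support overlap) defines "peaks in the window"; with
smooth unimodal cubic B-splines the two notions rarely differ and argmax
is unambiguous.

## Inference

`fitMle()` maximizes the likelihood by Nelder–Mead (robust to the
$-\infty$ feasibility cliffs) followed by BFGS polish with numerical
gradients, iterated while the polish still improves. Short tracks can
have separate likelihood basins — notably a $\delta^2 \to 0$ boundary
optimum where all variation is attributed to movement — so the optimizer
always runs from three moment-based starts that split the observed
increment variance differently between movement and error, keeping the
best. A user-supplied `init` (for example a nested model's solution, the
right warm start for AIC comparisons) is tried as an additional basin.
AIC is $2k - 2\log L$ with $k$ counting every coefficient plus two when
the origin is estimated; `compareAic()` refuses to compare fits of
different trajectories and breaks ties towards fewer parameters.

`fitMcmc()` samples the posterior under improper flat priors on the
feasible region. The kernel is a mixture: with probability 0.9 an
independence Metropolis–Hastings proposal from a multivariate $t_6$
centred on the MLE with the inverse-Hessian scale (refreshed from the
chain's own history at the middle and end of warmup), and with
probability 0.1 a random-walk step with the same shape and Robbins–Monro
scale tuning. The warmup adaptation also rebalances the mixture towards
the random walk when the independence proposal covers the posterior
poorly (skewed small-sample targets). The rationale for not using a pure
random walk is convergence quality: the target is low-dimensional and
near-Gaussian at realistic track lengths, and near-independent draws are
what make tight split-$\hat R$ values attainable at the default chain
lengths (4 chains, 5000 iterations, half warmup, thinning 10). All
adaptation freezes at the end of warmup, so retained draws come from a
valid Markov chain; runs are bit-reproducible given a seed. Convergence
is summarized by classic split-$\hat R$ (half-chains, between/within
variance ratio; not the rank-normalized variant, to match the
conventional 1.1 threshold): values above 1.1 indicate a poorly fitting
model or sampler, and chains frozen at distinct values report $\infty$
while degenerate zero-variance cases report `NA` rather than feigning
convergence.

## The simulator

`simulateTrajectory()` generates validation tracks whose defaults are the
study conditions the package is tested under: three movement states with
probabilities $(0.5, 0.2, 0.3)$ and rates $\sigma^2 = (0.3, 0.8, 2)$, a
continuous movement covariate $\sim U(0, 0.5)$ with slope 2; three
location-error categories with probabilities $(0.25, 0.5, 0.25)$ and
variances $\delta^2 = (3, 3.9, 6)$, a continuous error covariate
$\sim U(-1, 1)$ with slope 0.4; inter-fix gaps of
$1 + \text{Gamma}(3, \text{rate } 0.1)$ seconds, mean 31 s. The gamma's
second parameter is a rate, not a scale — only the rate reading gives the
stated mean. States and covariates are drawn once per segment (they
represent the whole interval), error categories and covariates once per
location. The true origin is $(0,0)$ and the first observed location adds
noise to it, so origin recovery is testable. The stored truth is coded
exactly as `buildDesign()` codes the covariates, making fitted
coefficients directly comparable.

`simulatePeriodicTrajectory()` generates ten-day tracks (by default) with
regular spacing, a circular-spline $\sigma^2(t)$ pattern averaged per
segment, and constant $\delta^2 = 10$. Regular spacing is a choice: the
phase coverage of the daily cycle, not the gap distribution, is what the
periodic experiments probe.

What the simulator does **not** emulate: behavioural persistence (states
are iid per segment, not a hidden Markov chain), home-range attraction,
burst sampling structure, heavy-tailed or autocorrelated GPS errors, and
habitat effects. Passing recovery tests therefore shows the estimator is
correct under the model's own assumptions — not that real tracks satisfy
them.

## Utilization distributions

`computeUd()` turns fitted variances into space use. Within segment $i$
at fraction $\alpha$, the position is Gaussian around the line between
the two observed anchors with isotropic variance
$\tau_i\,\alpha(1-\alpha)\,\sigma_i^2 + (1-\alpha)^2\delta_i^2 +
\alpha^2\delta_{i+1}^2$; the UD is the $\tau$-weighted average over
segments, integrated over $\alpha$ with 30-node Gauss–Legendre quadrature
(the integrand is smooth; the rule is deterministic). Bridges anchor on
the observed positions, the standard choice. Cell masses are density
times cell area, renormalized; the default margin is three standard
deviations of the largest bridge variance and the default cell size is
1/200 of the bounding-box extent. A segment mask supports conditional UDs
(day types) and excluding long gap-spanning segments, whose wide bridges
otherwise smear the surface. `contourThreshold()` returns
highest-density contours: cells sorted by mass, smallest prefix reaching
the level, ties broken deterministically by cell index (so a uniform grid
at 50% yields exactly half its cells).

## Numerical choices, problem sizes, limitations

* Quadrature: 21 nodes per knot span (splines), 30 nodes per segment
  (UD); both exact or effectively exact for their integrands.
* The acceptance experiments in `tests/` and `scripts/acceptance.R` use
  tracks of 100–5000 locations, 3 replicates where replication matters,
  and reduced MCMC lengths (2000/1000, thinning 10) for the
  recovery-coverage experiment; the sampler-health check runs the full
  5000/2500/10 settings. These sizes put parameter-recovery conclusions
  within routine desk-scale compute while keeping Monte-Carlo error well
  below the tested tolerances.
* The error-side slope of the continuous location-error covariate is the
  hardest parameter in the validation design: each $\delta_i^2$ is
  informed by essentially one noisy increment pair, so its estimator has
  a large sampling variance even at 5000 locations (the recovery
  experiments treat it accordingly).
* Limitations: isotropic Brownian motion only (no velocity persistence /
  OUF-type processes), no correlated axes, no spatial covariates or
  movement barriers, no automatic knot selection (AIC scans via
  `knotScan()` instead), and no outlier filtering — tracks are assumed
  pre-cleaned and in a planar metric projection.
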