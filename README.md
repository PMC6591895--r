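# bbcm — Brownian Bridge Covariates Model for animal movement

`bbcm` fits a continuous-time movement model for tracking data in which
**both** the Brownian motion variance of every track segment and the GPS
measurement-error variance of every location are linear functions of
covariates, and turns the fitted model into utilization distributions
(space-use surfaces). It is aimed at movement ecologists working with
high-frequency telemetry of animals whose movement rate varies — with
behavioural state, environmental drivers, or the time of day — and whose
location errors vary with recording conditions (HDOP, error classes,
tracking technology).

## The model

A track is $n+1$ planar locations $Z_0,\dots,Z_n$ (metres) at times with
lags $\tau_i$. The true path diffuses with per-segment variance
$\sigma_i^2$ ($m^2/s$, per axis); each observed location adds isotropic
Gaussian error with variance $\delta_i^2$ ($m^2$). Adjacent increments
$X_i = Z_i - Z_{i-1}$ share an observation's error, so per axis
$X \sim N(0, \Sigma_X)$ with symmetric **tridiagonal**

$$\Sigma_X[i,i] = \sigma_i^2\tau_i + \delta_i^2 + \delta_{i+1}^2,\qquad
  \Sigma_X[i,i+1] = -\delta_{i+1}^2 .$$

Covariates enter through design matrices,
$\sigma^2 = M_\sigma \beta_{\sigma^2}$ and
$\delta^2 = M_\delta \beta_{\delta^2}$ — intercepts, treatment-coded
factors (movement states, error categories), continuous drivers, and
circular cubic B-splines of the time of day (segment-averaged on the
movement side). The unknown trajectory origin $\gamma$ is estimated by
default by extending $\Sigma_X$ with one leading row/column
($\delta_1^2$, $-\delta_1^2$), which keeps the matrix tridiagonal. The
exact Gaussian log-likelihood is evaluated in $O(n)$ through the
$LDL^\top$ factorization of the bands (C++ core); parameters are
estimated by multi-start maximum likelihood or by adaptive MCMC with
split-$\hat R$ diagnostics, and models are compared by AIC. Fitted
variances feed a Brownian-bridge utilization distribution with 50%/95%
highest-density contours.

See the methods vignette (`vignettes/bbcm-methods.Rmd`) for the full
account: identifiability of splines and intercepts, positivity handling,
the sampler, the simulator's study conditions, and limitations.

## Worked example

Simulate a validation track under the package's default study conditions
(three movement states, three error categories, continuous drivers on
both sides, gamma-distributed gaps averaging 31 s), then recover the ten
generating parameters:

```r
library(bbcm)

sim <- simulateTrajectory(n = 2000, seed = 42)
sim@trajectory
#> Trajectory: 2000 locations (1999 segments), duration 61921.4 s
#>   mean time lag 30.98 s; bounding box x [-548.2, 50.4], y [-275.2, 71.2]
#>   location covariates: ecat, ecov
#>   segment covariates:  state, mcov

design <- buildDesign(sim@trajectory, sim@modelSpec)
fit <- fitMle(sim@trajectory, design)
fit
#> BBCM maximum-likelihood fit ('bbcm')
#>   logLik -13161.707, k = 10, AIC 26343.414
#> sigma2.(intercept)    sigma2.state.s2    sigma2.state.s3        sigma2.mcov
#>            0.27840            0.40076            1.79260            2.12770
#> delta2.(intercept)     delta2.ecat.c2     delta2.ecat.c3        delta2.ecov
#>            3.67880            0.68058            2.63600            0.35247
#>            gamma.x            gamma.y
#>           -0.75984           -0.36090
```

The generating values were $\sigma^2$ intercept 0.3 with state contrasts
0.5 and 1.7 and movement slope 2; $\delta^2$ intercept 3 with category
contrasts 0.9 and 3 and error slope 0.4; origin (0, 0). Movement
parameters come back tightly; error-side parameters are intrinsically
noisier (each $\delta_i^2$ is informed by a single noisy increment pair),
which the posterior intervals make visible:

```r
chains <- fitMcmc(sim@trajectory, design, iterations = 2000, warmup = 1000,
                  seed = 42)
chains
#> PosteriorChains: 100 draws x 4 chains x 10 parameters
#>   warmup 1000, thin 10; post-warmup acceptance 0.46, 0.42, 0.42, 0.43
#>   max split R-hat 1.0059

subset(posteriorIntervals(chains), level == 0.95)
#>             parameter level  lower median upper
#>    sigma2.(intercept)  0.95  0.190  0.279 0.381
#>       sigma2.state.s2  0.95  0.261  0.411 0.577
#>       sigma2.state.s3  0.95  1.545  1.794 2.077
#>           sigma2.mcov  0.95  1.706  2.149 2.494
#>    delta2.(intercept)  0.95  2.461  3.917 5.513
#>        delta2.ecat.c2  0.95 -1.330  0.533 2.285
#>        delta2.ecat.c3  0.95  0.174  2.439 4.863
#>           delta2.ecov  0.95 -1.109  0.183 1.691
#>               gamma.x  0.95 -5.015 -0.757 3.410
#>               gamma.y  0.95 -4.215 -0.276 3.051
```

All ten 95% intervals cover their generating values. From here,
`computeUd()` + `contourThreshold()` give space-use surfaces and
contours; `knotScan()` chooses the number of daily-spline knots by AIC;
`duplicateSplineColumns()` builds window-restricted day-type
interactions (e.g. hot-day mornings); `runBbcm()` (or the thin CLI in
`inst/scripts/bbcm.R`) drives the same steps from a YAML config.

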