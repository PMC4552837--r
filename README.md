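# buvspatial

Bayesian spatial presence–absence models for baited underwater video
(BUV) surveys.

## What this is for

Marine-park monitoring programs deploy baited video rigs at clustered
coastal sites, often revisiting sites across seasons, and record whether
a target species (e.g. snapper) appears during each deployment. Analysts
typically model presence with a logistic regression on habitat and
management covariates and *assume* deployments are independent given
those covariates. Unmeasured, spatially smooth drivers make that
assumption doubtful. `buvspatial` is for ecologists and biostatisticians
who want to test and account for residual spatial dependence in such
binary survey data.

The package fits and compares two models for presence `Y_t(s)` at site
`s` in period `t`:

    Non-spatial:  logit(p_t(s)) = X_t(s)' β
    Spatial:      logit(p_t(s)) = X_t(s)' β + η(s)

with `η` a zero-mean Gaussian process over site locations with
exponential covariance `Cov(η(s_i), η(s_j)) = σ² exp(−φ ||s_i − s_j||)`
(planar meters). Priors: `β_i ~ N(0, 2.5)`, `1/φ ~ Unif(50, 1500)` m,
`σ² ~ InvGamma(2, 2)`. The effective range — where correlation drops to
0.05 — is `3/φ`.

Inference is Pólya-Gamma data-augmentation Gibbs sampling (exact
conditional updates for `β`, `η`, `σ²`; random-walk Metropolis on the
logit-transformed `1/φ`), implemented in C++ and fully seeded. The
package also provides:

* a synthetic survey generator (clustered sites in a coastal band,
  spatially clumped habitat, GP-driven presence) so the whole pipeline
  is testable without field data;
* per-draw predicted probabilities and posterior LL / MSE / ROC-AUC
  model comparison with credible intervals;
* location-blocked k-fold cross-validation with per-draw kriged
  (conditional GP) random effects at held-out sites;
* posterior reporting: odds ratios (two conventions, side by side),
  HPD intervals, effective-range summaries, and gridded posterior-mean
  spatial-effect surfaces written as ASCII grids;
* a thin command-line pipeline (`inst/cli/buvspatial.R`) with
  `simulate`, `fit`, `evaluate`, `cv` and `report` subcommands.

## Worked example

```r
library(buvspatial)

sim <- simulate_survey(sim_config(seed = 1))   # 174-site synthetic survey
sim$data
#> BUV survey dataset: 539 observations at 174 sites
#>   presence rate: 0.468

fit <- fit_model(sim$data,
                 config = fit_config(spatial = TRUE, n_retained = 2000,
                                     burn_in = 500, thin = 5, seed = 2))
fit
#> Spatial Bayesian logistic fit: 2000 retained draws, 174 sites
#>   phi acceptance rate: 0.341  | posterior median effective range: 1306.3 m

summarize_coefficients(fit)[c(2, 6, 8, 9), c(1:3, 5:6)]
#>         name posterior_mean ci_low ci_high significant or_mean
#>    green_old         -0.803 -2.711    1.06       FALSE    0.72
#>         kelp          2.043  1.296    2.86        TRUE    8.35
#>  coffee_rock          1.779  0.905    2.72        TRUE    6.59
#>       winter          0.851  0.438    1.29        TRUE    2.40

metric_summaries(sim$data$observations$presence,
                 predict_probabilities(fit, sim$data))
#>  metric posterior_mean interval_low interval_high
#>      LL       -293.723     -308.168      -278.254
#>     MSE          0.184        0.172         0.195
#>     AUC          0.794        0.765         0.820
```

Reading this: kelp multiplies the odds of presence by ~8 and coffee rock
by ~7 at these simulation settings, protection status is not
distinguishable from zero, and the spatial model separates presences
from absences within-sample with AUC ≈ 0.79. The survey was simulated
with a 2000 m effective range; the posterior median lands at ~1.3 km
with a wide, right-skewed HPD interval — binary data identify the range
only loosely, which is exactly why the package reports median + HPD:

```r
effective_range_summary(fit)
#> effective range: median 1306.3 m, mean 1526.5 m, 95% HPD (278.3, 3455.5)
```

For out-of-sample comparison use `cross_validate(sim$data, k = 5)`,
which blocks folds by site so repeat visits never leak across the split
and kriges `η` to held-out sites per posterior draw.

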