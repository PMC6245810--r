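# ghostsurv

How many observations is a parametric assumption worth?

When estimating cumulative risk from right-censored time-to-event data, a
nonparametric estimator makes almost no assumptions but pays for that
flexibility in precision; a parametric model is tighter, but only because
its shape constraint injects information beyond the data. `ghostsurv`
expresses that injected information as an **effective sample size**: it
adds fictitious "ghost" pseudo-observations to the nonparametric sample —
realized as a uniform case-weight increment of `1/N` per ghost, which
leaves the estimated curve untouched while shrinking its variance — until
the nonparametric 95% confidence-limit width at a chosen time drops
strictly below the parametric model's width. The resulting count `M` is
the number of hidden observations underlying the parametric model's
efficiency. The package is aimed at epidemiologists and biostatisticians
who want the bias/variance trade-off between model classes stated in
subjects rather than in abstract variance ratios.

## The method

* **Nonparametric arm.** Weighted Nelson-Aalen cumulative hazard
  `H(t_i) = Σ_{j≤i} d_j/Y_j` over distinct event times, Poisson-type
  variance `V = Σ d_j/Y_j²`, risk `F = 1 − e^{−H}`, delta-method
  `SE(F) = e^{−H}√V`, identity-scale Wald limits `F ± z₀.₉₇₅·SE`.
* **Parametric arm.** Censored maximum likelihood for the nested
  accelerated failure time families — generalized gamma
  `(mu, sigma, kappa)`, Weibull `(kappa = 1)`, exponential
  `(kappa = sigma = 1)` — with delta-method limits for `F(t)` from the
  numerically evaluated observed information.
* **Ghosts.** With every weight scaled by `(N + M)/N`, each SE is divided
  by `√(1 + M/N)` *exactly*. The minimal `M` with
  `width₀/√(1 + M/N) < width_parametric` is found by one-by-one search
  and verified against the closed form
  `M ≈ N((width₀/width_target)² − 1)`, with ties at the boundary decided
  by direct predicate evaluation (the stopping rule is strict).

The motivating cohort (1164 HIV-positive women followed ~10.8 years for
AIDS or death) is confidential, so a seeded synthetic-cohort generator
emulates it: generalized-gamma event times calibrated to a two-year risk
of 0.22 with a decreasing hazard, 5%/year loss to follow-up, and
administrative censoring at 10.83 years.

## Worked example

```r
library(ghostsurv)

co <- generate_cohort(default_wihs_scenario(seed = 1))
fit <- fit_parametric(co, "gengamma")
target <- cl_width(parametric_risk_curve(fit, 2), 2)
find_ghosts(co, target, eval_time = 2)
#> <ghost_result>
#>   M = 281 pseudo-observations over N = 1164 (uniform weight 1.241409)
#>   width at t = 2: 0.049783 (M = 0) -> 0.044681, target 0.044693
```

The nonparametric two-year width 0.0498 must shrink below the generalized
gamma's 0.0447; that takes 281 ghosts, i.e. the three-parameter shape
assumption is worth about 280 extra subjects here. The full comparison:

```r
tab <- build_comparison_table(co, eval_time = 2)
```

| approach      |    n |    m |  risk | 95% CLs        | CL difference | avg CL difference |  rmse |
|---------------|-----:|-----:|------:|----------------|--------------:|------------------:|------:|
| nonparametric | 1164 |    0 | 0.235 | 0.210, 0.260   |         0.050 |             0.046 | 0.013 |
| gengamma      | 1164 |    0 | 0.235 | 0.213, 0.258   |         0.045 |             0.041 | 0.011 |
| nonparametric | 1164 |  281 | 0.235 | 0.212, 0.257   |         0.045 |             0.041 | 0.011 |
| weibull       | 1164 |    0 | 0.227 | 0.207, 0.248   |         0.041 |             0.039 | 0.013 |
| nonparametric | 1164 |  537 | 0.235 | 0.214, 0.255   |         0.041 |             0.038 | 0.011 |
| exponential   | 1164 |    0 | 0.151 | 0.139, 0.162   |         0.024 |             0.027 | 0.085 |
| nonparametric | 1164 | 3941 | 0.235 | 0.223, 0.247   |         0.024 |             0.022 | 0.006 |

Read it row-blockwise: each parametric row is followed by the
ghost-weighted nonparametric row matched to its width. The weighted rows
re-estimate the *same* risk (0.235) with ever-narrower limits — ghosts
change precision, never the curve. The generalized gamma tracks the
nonparametric risk and is cheap to match (281 ghosts); the exponential is
spectacularly precise (width 0.024) but biased low at two years (0.151
vs 0.235, hence its RMSE of 0.085), and matching it costs 3941 ghosts —
more than quadrupling the sample buys the same precision without the
bias.

A thin command-line wrapper over these functions ships at
`inst/cli/ghostsurv.R` (subcommands `simulate`, `fit`, `ghosts`,
`compare`).

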