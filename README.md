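# firefreq

Fire-frequency analysis for landscapes monitored with multi-year burned-area
maps, built around the **discrete lognormal fire-interval model**.

In fire-prone savannas the same patch of vegetation burns again and again,
and the quantity that matters for management is not whether fire occurs but
*how often*: the distribution of the fire-free interval `T` (whole years
between successive fires at a point), the survival distribution
`A(t) = P(T > t)` (chance a patch stays unburned longer than `t` years), the
hazard of burning `lambda(t) = f(t) / A(t-1)` (chance of burning at fuel age
`t` given survival to its start), and rotation statistics such as the fire
rotation period `FRP = N * S / sum(A_y)` and the annual percent area burned
`APAB = 100 / FRP`. `firefreq` estimates all of these, per land-cover class,
from a stack of annual burn masks, modelling `T = ceiling(X)` with
`X ~ Lognormal(mu, sigma)`:

    f(t)      = Phi((ln t - mu)/sigma) - Phi((ln(t-1) - mu)/sigma)
    A(t)      = 1 - Phi((ln t - mu)/sigma)
    lambda(t) = f(t) / A(t-1)

A short record inevitably censors many intervals — fire-free periods cut off
by the start or end of the observation window, and points that never burned
at all. The fitting function handles complete, right-censored and
left-censored observations in one maximum-likelihood framework, treating the
record-start observations as forward recurrence times of the equilibrium
renewal process (ignoring censoring, or treating it naively, visibly biases
the estimates — see the methods vignette). A Hollander–Proschan style
goodness-of-fit test adapted to discrete, record-window data, a
renewal-process landscape simulator for validation, and a reporting pipeline
round out the workflow:

| function | role |
|---|---|
| `fire_fit()` | censored MLE of `(mu, sigma)`; returns a `firefit` with `print`, `summary`, `coef`, `vcov`, `logLik`, `predict`, `plot`, `simulate`, `residuals` methods |
| `extract_intervals()` / `point_intervals()` / `read_fire_points()` | point-grid sampling of a burn-mask stack into censored interval observations |
| `dfireint()` / `sfireint()` / `hfireint()` / `fire_descriptors()` | interval pmf, survival, hazard; median / mode / turning point |
| `hp_test()` | censored-data goodness of fit, standardized to a normal scale |
| `fire_rotation()` / `burn_count()` | FRP and APAB per class; times-burned maps |
| `simulate_history()` / `simulate_intervals()` | per-class renewal landscape simulator |
| `fire_report()` | end-to-end per-class pipeline writing summary tables and curves |
| `jalapao_classes()` | published reference estimates for the seven Cerrado land-cover classes of Jalapão State Park (1997–2008) |

## Worked example

Simulate a 45×45-cell, 12-year burn record from a shrub-savanna-like regime
(`mu = 0.82`, `sigma = 0.66`), sample it on a 500 m point grid, and fit:

```r
library(firefreq)

cfg  <- fire_sim_config(45, 45,
                        data.frame(class = "SS", meanlog = 0.82,
                                   sdlog = 0.66, fraction = 1),
                        years = 12, burn_in = 50, seed = 42)
grid <- simulate_history(cfg)
iv   <- extract_intervals(grid, spacing_m = 500)
fit  <- fire_fit(iv)
fit
#> Discrete lognormal fire-interval model
#> Call:  fire_fit(x = iv)
#>
#> meanlog   sdlog
#>  0.8226  0.6566
#>
#> Observations: 5302 complete, 2025 right-censored, 2015 left-censored
#> Log-likelihood: -13843.8
#> Median 3 yr, mode 2 yr, hazard turning point 4 yr
```

The fit recovers the generating parameters to the second decimal, and the
derived descriptors read directly as management quantities: the median
fire-free period is 3 years, the most probable interval is 2 years, and the
hazard of burning peaks at fuel age 4 — after which older patches become
*less* likely to burn, the signature fuel-age pattern of savanna fire
regimes. Goodness of fit and rotation statistics:

```r
hp_test(iv, fit, B = 300, seed = 1)
#> 	Hollander-Proschan goodness-of-fit test (discrete lognormal null,
#> 	parametric bootstrap)
#> data:  iv
#> z = 0.42732, ... p-value = 0.6691

fire_rotation(grid)[, c("class", "area_ha", "burned_ha", "frp", "apab")]
#>   class area_ha burned_ha      frp     apab
#> 1    SS   50625    182925 3.321033 30.11111
#> 2   all   50625    182925 3.321033 30.11111
```

The p-value of 0.67 says the interval sample is consistent with the fitted
discrete lognormal; the rotation period of 3.3 years means an area equal to
the whole burnable landscape burns roughly every 3.3 years (30% per year),
and matches the model's mean interval `fireint_mean(0.82, 0.66)` = 3.32, as
renewal theory says it must. With real data, replace the simulated grid with
`fire_history(burns, land_cover, years, cell_size)` built from your rasters,
or feed per-point fire-year lists through `read_fire_points()`; the per-class
pipeline `fire_report(grid, out_dir = "out")` writes the summary table
(class, areas, FRP, APAB, `mu`, `sigma`, median, mode, turning point, GOF
statistic and p-value) plus full-precision curve exports.

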