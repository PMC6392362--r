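# occpart

Dynamic correlated-detection occupancy models with deviance partitioning.

`occpart` is for ecologists who want to ask not "where does a species
occur?" but "what drives the *changes* in where it occurs?" — and to
split the answer between climate change and land-cover change. It
reimplements, as a tested R package, a full inference chain for
stop-level roadside survey data of the North American Breeding Bird
Survey (BBS) type: ~50 binary detection records per route per breeding
season, with imperfect detection, spatially correlated detections along
the route, and route-level detection heterogeneity.

## The model

Route occupancy follows a Markov chain across seasons — initial occupancy
ψ, colonization γ_t = Pr(z_{t+1}=1 | z_t=0), extinction
ε_t = Pr(z_{t+1}=0 | z_t=1) — with equilibrium occupancy γ/(γ+ε).
Conditional on occupancy, availability at consecutive stops follows a
first-order Markov chain (onset θ, persistence θ′), and an available stop
is detected with probability p1 or p2 according to a two-class route-level
finite mixture with weight π. The likelihood is exact (nested forward
recursions, compiled in C++).

The headline statistic is the analysis-of-deviance ratio

    RDev² = (Dev(M_null) − Dev(M_cov)) / (Dev(M_null) − Dev(M_full))

over a six-model set on (γ, ε): intercept-only (1), spatial covariate
means + year dummies (2, the full model), spatial means only (3, the
null), and spatial means plus temporal deviations of climate (4), habitat
(5), or both (6). RDev² measures how much of the fully year-varying
model's temporal signal a covariate explains. Goodness of fit is checked
with Hosmer–Lemeshow tests on naive colonization/extinction rates, and
climate covariates (thermal-stress hours outside the 18–38 °C
thermoneutral zone) are engineered from daily temperature extremes by
hourly interpolation, breeding-cycle aggregation and a 15-year trailing
moving average.

## Worked example

Simulate a desk-scale BBS-like world (150 routes × 8 years × 15 stops,
high occupancy, low extinction, two detection classes), fit the six-model
set, and partition the deviance:

```r
library(occpart)

design <- simulation_design(n_routes = 150, n_years = 8, n_stops = 15,
                            seed = 7)
sim <- simulate_dataset(design)

base  <- model_spec(psi = list(t_intercept(), t_cov("habitat", "mean")))
specs <- build_model_set(base, sim$data$years)
f3    <- fit_occu(sim$data, specs$model3, sim$covariates, n_starts = 1)
fits  <- lapply(specs, function(sp)
  fit_occu(sim$data, sp, sim$covariates, n_starts = 1,
           start = expand_start(f3, sp)))
fits$model3 <- f3

anodev_table(fits)
#>  model ... delta_neg2ll rdev2_pct neg2ll n_params  aic
#>      6              5.941    142.45   8435       21 8477
#>      4              2.085    114.90   8439       19 8477
#>      2              0.000    100.00   8441       27 8495
#>      5             -2.439     82.57   8444       17 8478
#>      3            -13.996      0.00   8455       15 8485
#>      1            -23.030        NA   8464        9 8482
```

Model 2 (year dummies) improves on the spatial-only Model 3 by 14.0
deviance units; the deviation-covariate models recover more than all of
that (RDev² > 100%) — a live illustration of the documented caveat that
models 4–6 are only *quasi*-nested in Model 2, since route-by-year
deviations span directions that common year effects cannot. On the real
study data the published values are RDev² = 19.6% (climate) and 0.4%
(habitat) for Eastern Wood Pewee, 5.6% and 0.1% for Red-eyed Vireo; the
package reproduces that arithmetic exactly from the published deviance
offsets (see `anodev_from_offsets()`).

Goodness of fit on naive turnover:

```r
g <- gof_naive_rates(fits$model2, sim$data, sim$covariates)
g$colonization[c("chi2", "df", "p")]
#> chi2 = 5.23, df = 7, p = 0.63     # no lack of fit, as expected
```

A full file-based run (CSV in, CSV/JSON bundle out) goes through
`run_config()` + `run_pipeline()`, or the CLI:

```sh
Rscript inst/cli/occpart.R simulate --out data/ --routes 100 --years 8 --stops 20 --seed 1
Rscript inst/cli/occpart.R fit --config run.json
```

## Documentation

The methods vignette
(`vignettes/occupancy-deviance-partitioning.Rmd`) describes the model,
its assumptions, every tunable convention (first-stop availability,
deviation timing, standardization order, GOF conditioning), the synthetic
world the generator states, and known limitations.
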