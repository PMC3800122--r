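# perchboom

Logistic null models for the Nile perch invasion of Lake Victoria.

Nile perch (*Lates niloticus*) were introduced to the Ugandan side of
Lake Victoria in 1954, yet the species only became dominant in catches
between 1979 and 1987 — a 25-year "lag" that has fuelled hypotheses
about Allee effects, depensation by native haplochromines, and
cannibalism. `perchboom` asks the null question first: **when should
the boom have happened anyway**, given plain logistic growth

  dN/dt = r N (1 − N/K),

with an independently estimated growth rate r = 0.73 yr⁻¹, a carrying
capacity K = 963,200 t (14 t/km² over 68,800 km²), and an inoculum of
four 20 cm fish (N₀ = 0.00039 t)? The closed form

  N(t) = K / (1 + ((K − N₀)/N₀) e^(−rt))

puts the first crossing of 5% of K ("onset of the boom") 25.6 years
after introduction — calendar year 1979 — and the crossing of 95% of K
("peak") 8 years later, in 1987. The apparent lag is just the quiet
part of exponential growth; no trigger is required.

The package is aimed at quantitative ecologists who want that argument
as tested, reusable code: the closed-form and ODE-integrated core,
two-phase depensation scenarios, 1-D/2-D lattice dispersal models with
migration-rate calibration, elasticity analysis of boom timing, a
synthetic CPUE survey generator with a logistic fitter for
parameter-recovery studies, and a config-driven scenario runner.

## Worked example

```r
library(perchboom)

ev <- event_years(victoria_params())
ev
#> Boom onset: 1979   peak: 1987
#>   (crossing times 25.59 and 33.66 yr after introduction)

threshold_year(victoria_params(), 400)
#> [1] 1972        # matches the 402 t standing-stock estimate of 1969-70

depensation_grid(victoria_params())[1:3, ]
#>      f   c onset_year peak_year
#> 1  1.0 0.5       1979      1987
#> 2  0.9 0.5       1982      1990
#> 3  0.8 0.5       1985      1993

sensitivity_report(victoria_params())
#> Elasticities of boom-onset time
#>  parameter elasticity            method
#>          r   -1.00000          analytic
#>         N0   -0.05352          analytic
#>          K    0.05352          analytic
#>          r   -1.00000 finite-difference
#>         N0   -0.05352 finite-difference
#>          K    0.05352 finite-difference
#> Ratio |e_r| / |e_N0| = 18.68 (20 to one significant figure)
```

The grid shows how a reduced growth rate (f·r below a biomass
threshold c·B_ini, with B_ini = 5% of K) delays onset and peak; the
elasticities show the onset time is controlled by the growth rate —
a change in the stocking size matters about twenty times less.

Scenario configurations (YAML or JSON) drive the same computations
end to end:

```r
cfg <- system.file("extdata/configs/kyoga.yaml", package = "perchboom")
run_scenarios(cfg)$summary
#>       scenario     type status onset_year peak_year detail
#> 1 kyoga_backcast logistic     ok       1968      1977
```

The Lake Kyoga back-cast (147 fish of assumed 30 cm, 1955,
K = 24,080 t) predicts a boom starting in 1968, at least five years
after the boom actually observed there — evidence that habitat, not
just arithmetic, shapes invasion speed.

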