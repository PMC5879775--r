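# sahelsim

Stochastic, spatially explicit, individual-based simulation of
*Anopheles gambiae* s.l. metapopulation dynamics on networks of human
settlements in seasonally arid West Africa — for vector ecologists and
modellers asking how mosquito populations survive a six-month dry season
and reappear, settlement after settlement, with the first rains.

Every settlement hosts a local population of juveniles, males, virgin and
mated females, updated daily by binomial/Poisson draws. A juvenile survives
each of the `T_L` days of development with probability

    p_s = [alpha(x,t) / (alpha(x,t) + J_T)]^(1/T_L) * (1 - mu_J)

so that `alpha(x,t)` is the juvenile count at which density-dependent
mortality over development is 50%. That carrying-capacity scale is driven
by weekly rainfall and nearby water courses,

    alpha(x,t) = alpha0(x)
               + alpha1 * (1 - exp(-phi * r(x,t)))
               + alpha2 * (1 - exp(-kappa * [W_p + W_n (1 - exp(-delta * r(x,t)))]))

with `W_p`/`W_n` the perennial and intermittent water-course length within
`L_w` of the settlement and `alpha0` an optional lognormal cryptic
permanent-habitat term. Virgin females mate with daily probability
`M / (beta + M)`; mated females lay Poisson(`theta`) eggs per day. Adults
disperse to settlements within `L_D` km with daily probability `d`
(kernel weight `L_D - d_ij`), and two windowed dry-season mechanisms can be
switched on: aestivation of mated females (`psi`, `mu_E`) and wind-aligned
NE<->SW long-distance migration (`d_M`, `mu_M`). The package classifies
persistent settlements, measures rainy-season occupancy, and contrasts the
local-dynamics signatures of the competing dry-season hypotheses.

A synthetic-landscape generator (Thomas-clustered settlements, random-walk
river networks in two perennial classes, gradient-plus-season rainfall
grids) makes every analysis runnable offline; loaders for settlement CSV,
water-course GeoJSON and daily rainfall CSV accept real data in the same
containers. NetCDF rainfall and ESRI shapefiles are not read directly:
convert to the CSV/GeoJSON dialects described in `?load_rainfall` and
`?load_water_courses`.

## A worked example

```r
library(sahelsim)

ls <- generate_landscape(reference_scenarios()[["arid-north"]])
cf <- simulation_config(ls, years = 3, burn_in_years = 2, replicates = 3,
                        seed = 42, record = "summary")

persistent <- classify_persistent(cf)
sum(persistent)
#> [1] 52

runs <- list()
for (d in c(0, 0.005, 0.034, 0.1)) {
  runs[[as.character(d)]] <- run_simulation(
    simulation_config(ls, years = 3, burn_in_years = 2, replicates = 3,
                      seed = 42, movement = movement_params(d = d),
                      record = "summary"))
}
sapply(runs, function(r) mean(unoccupied_fraction(r)$fraction))
#>     0 0.005 0.034   0.1
#> 0.602 0.456 0.422 0.396
```

52 of 200 settlements persist in complete isolation (they sit on perennial
water or in the year-round-rain south); with no dispersal 60% of
settlements lack mosquitoes on 19 October, and the unoccupied fraction
falls as the daily dispersal probability rises through the range estimated
from mark-release-recapture studies (0.005–0.034) — the island–mainland
recolonisation mechanism. Switching on aestivation
(`aestivation_params(psi = 0.01, mu_E = 0.9)`) or migration
(`movement_params(d = 0.01, d_M = 0.001, mu_M = 0.99)`) rescues most of
the remaining arid-north settlements; `local_dynamics_profiles()` then
separates the hypotheses by their seasonal signatures (early synchronous
resurgence under aestivation, later and more variable under migration, a
nonzero dry-season floor with cryptic permanent habitat).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/sahelsim generate-landscape --preset arid-north --out-dir ls/
Rscript inst/cli/sahelsim simulate --config cfg.yaml --out out/
```

The methods vignette (`vignettes/dry-season-persistence.Rmd`) documents the
model, the daily event order, all parameters and their defaults, the
synthetic-landscape assumptions and the package's design decisions.

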