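---
title: "Modelling dry-season persistence of Anopheles populations on settlement networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dry-season persistence of Anopheles populations on settlement networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahelsim)
```

## The scientific problem

Across semi-arid West Africa, *Anopheles gambiae* s.l. populations appear in
essentially every human settlement during the rainy season, yet in much of
the region — above all the Sahel — larval habitat vanishes for six or more
months each year and adult mosquitoes seem to disappear with it. Three
mechanisms are commonly invoked to explain the annual reappearance:
**aestivation** (dormancy of mated females in shelters), **local dispersal**
from neighbouring settlements that retain year-round breeding habitat, and
**long-distance wind-assisted migration**. A fourth possibility is the
existence of **cryptic small permanent larval sites** (wells, containers,
small reservoirs) absent from water-body databases.

`sahelsim` implements a stochastic, spatially explicit, individual-based
metapopulation model in which each human settlement hosts a local mosquito
population, and the four mechanisms can be switched on independently. The
package also ships a synthetic-landscape generator so that every analysis is
reproducible without geographic downloads.

## The demographic model

Each settlement's population comprises juveniles (egg through
pre-reproductive adult, a fixed `T_L`-day stage tracked in daily age
classes), adult males `M`, virgin females `V` and mated females `F`. All
counts are integers updated daily by draws from the corresponding
probability distributions.

A juvenile survives one day with probability

$$p_s = \left(\frac{\alpha(x,t)}{\alpha(x,t) + J_T}\right)^{1/T_L} (1 - \mu_J),$$

where `J_T` is the settlement's total juvenile count and `alpha(x,t)` is the
larval-competition scale: the juvenile density at which cumulative
density-dependent mortality over the `T_L` days of development is exactly
one half. Survivors of age `T_L` emerge as males or virgin females with
equal probability. Adults die with daily probability `mu_A`; virgins mate
with daily probability `p_m = M / (beta + M)` and move to the mated class;
each mated female lays a Poisson(`theta`) clutch per day.

The carrying-capacity scale is

$$\alpha(x,t) = \alpha_0(x) + \alpha_1\!\left(1 - e^{-\phi\, r(x,t)}\right)
 + \alpha_2\!\left(1 - e^{-\kappa\,[W_p(x) + W_n(x)(1 - e^{-\delta\, r(x,t)})]}\right),$$

combining rain-fed ephemeral pools (saturating at `alpha1` with weekly
rainfall `r`), and breeding habitat along water courses within a radius
`L_w` of the settlement — perennial length `W_p` counts fully, intermittent
length `W_n` is discounted by a rain-replenishment factor so that under
heavy rain it provides the same habitat density as permanent water. The
optional first term `alpha0(x)` represents cryptic small permanent sites,
drawn lognormally across settlements from a natural-scale mean and variance
(`alpha0_mean`, `alpha0_var`) and zero in the baseline model. Rainfall is a
weekly forcing, so `alpha` is recomputed at week boundaries only.

### Movement

Adults of all classes disperse locally each day with probability `d`, to a
neighbouring settlement within radius `L_D` chosen with probability
proportional to `L_D - d_ij`. Dispersal from isolated settlements is
therefore typically longer-range than from settlements inside dense
clusters. During two annual windows, mated females additionally initiate
long-distance migration with daily probability `d_M` — north-east to
south-west in the first window, the reverse in the second, following the
seasonal wind regimes — dying en route with probability `mu_M` and
otherwise landing at a settlement drawn uniformly from the 90-degree
directional wedge extending from the focal site to the edge of the region.
Aestivation is likewise windowed: mated females enter dormancy with daily
probability `psi` during the entry window, survive it with probability
`1 - mu_E`, and re-emerge on a uniform-random day of the emergence window.

### Daily event order

The update order within a day is: (1) weekly `alpha` refresh; (2) juvenile
survival and ageing; (3) emergence; (4) adult survival; (5) mating;
(6) aestivation exit, then entry; (7) oviposition; (8) local dispersal,
then migration. Newly emerged females can therefore mate on their first
day — virgin females are assumed to mate almost immediately when males are
abundant — and movement last keeps each day's demography local. One
counting convention deliberately differs: `lifetime_movement_probability()`
counts a dispersal attempt made on an adult's death day as a move, because
that is how a mark-release-recapture study would count it; this gives the
closed form `d / (d + mu_A - d mu_A)` used to translate recapture estimates
into the daily rate `d`.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `T_L` | egg-to-adult duration | 12 | days |
| `mu_J` | density-independent juvenile mortality | 0.03 | /day |
| `mu_A` | adult mortality | 0.125 | /day |
| `theta` | eggs per mated female | 9 | /day |
| `beta` | males at which mating probability is 0.5 | 100 | individuals |
| `alpha1` | rainfall-term asymptote | 20000 | juveniles |
| `alpha2` | water-course-term asymptote | 40000 | juveniles |
| `phi` | rainfall saturation rate | 0.05 | /mm |
| `kappa` | water-density saturation rate | 0.1 | /km |
| `delta` | intermittent-course replenishment rate | 0.05 | /mm |
| `L_w` | water-search radius | 2 | km |
| `d` | local dispersal probability | 0.01 | /day |
| `L_D` | dispersal neighbourhood radius | 10 | km |
| `psi`, `mu_E` | aestivation entry rate, dormancy mortality | 0, 0.9 | /day, prob |
| `d_M`, `mu_M` | migration initiation rate, en-route mortality | 0, 0.99 | /day, prob |

`mu_A = 0.125` and `beta = 100` are fixed by the study design (`beta` set
deliberately low so females nearly always mate on their first day in all
but tiny populations). The remaining values are calibration placeholders
chosen by us, not field estimates: `T_L`, `mu_J` and `theta` sit in the
range reported for *An. gambiae* s.l. in the field literature
(development ~10–14 days, tens of eggs per gonotrophic cycle every 2–3
days); the carrying-capacity constants were chosen so that a settlement
with 20–60 mm of weekly rain supports rainy-season populations of order
10^4–10^5 juveniles and a few thousand adults, which is the scale of
village populations reported in entomological surveys; `L_D = 10` km spans
the distances over which inter-village recaptures are observed, and
`L_w = 2` km is a typical female flight range to larval habitat. All of
them live in one place (the parameter constructors, and the YAML config
read by `read_config_yaml()`), and every analysis in the package states the
values it used.

Aestivation and migration window dates are documented guesses on a 365-day
no-leap calendar: entry (280, 340) as populations collapse after the rains,
emergence (160, 200) just before and at rain onset; migration NE→SW in
(1, 60) with the dry-season Harmattan and SW→NE in (160, 220) with the
monsoon onset.

## The synthetic landscape generator

`generate_landscape()` emulates the three geographic inputs of the study
region — clustered settlements, a two-class water-course network, and a
0.5-degree weekly rainfall grid — inside a square of configurable side:

* **Settlements** follow a Thomas cluster process (uniform parents,
  Gaussian offspring dispersion) conditioned on the exact settlement count;
  occupancy analyses depend on heterogeneous settlement density, so uniform
  points would be an inadequate stand-in. Explicit cluster layouts can be
  supplied instead, which the island–mainland preset uses.
* **Water courses** are ~1 km-step random walks reflected at the region
  boundary, laid down until each class reaches its declared density (km per
  100 km^2); perennial courses can be biased toward, or confined to, the
  south.
* **Rainfall** is a Gaussian seasonal bump (centre and width in days)
  scaled by a linear north–south gradient, plus an optional year-round
  southern floor that decays northward, all multiplied by a shared
  lognormal mean-one yearly factor. Interannual autocorrelation is
  available as an AR(1) switch on the log multiplier, off by default:
  historical rainfall in the region is autocorrelated, but independent
  years are the simpler null and the switch isolates that assumption.
  Weekly totals below 0.1 mm are treated as dry.

Four presets (`reference_scenarios()`) span the regimes of interest:
`wet-south` (year-round southern rain), `arid-north` (fully seasonal north
with a 6+ month dry season; the work-horse for the dispersal, aestivation
and migration experiments), `sahel-remote` (a northern cluster more than
30 km from perennial water, the situation where dispersal explanations
fail), and `island-mainland` (an explicit persistent mainland plus island
clusters at controlled distances and densities, used to separate the
distance-to-source and settlement-density correlates of occupancy — it
includes sparse-but-near and dense-but-far clusters precisely so the two
correlates disagree).

What the generator does *not* emulate: real settlement densities (the
OCHA data hold ~4 settlements per 100 km^2; the presets hold ~0.2, so that
a ten-year, multi-configuration experiment runs in minutes), spatially
correlated rainfall anomalies, river topology (walks can cross), and
settlement size structure. Passing tests on these landscapes therefore
demonstrates the mechanisms and their interplay at reduced scale, not
calibrated regional predictions; marginal effects that average out over
42,000 settlements (for example the 30-day longevity cap, which trims
about 1.7% of adult lifespan) are relatively amplified on a sparse
200-settlement landscape.

## Simulation protocol and numerical choices

Runs are day-indexed from the start of the rainfall series with a 365-day
no-leap calendar. Every settlement is seeded with 500 males and 500 mated
females on day-of-year 160 (the rainy-season build-up) of year 1, two
burn-in years let unsustainable populations die out and sustainable ones
equilibrate, and subsequent years are the output period. The standard
experiment size used throughout the tests is the `arid-north` preset
(200 settlements), five simulated years (two burn-in + three output) and
ten replicates, which keeps the full acceptance battery within a desk-scale
compute budget while leaving clear Monte-Carlo margins.

Other numerical conventions:

* **Persistence** is classified by a ten-year run with dispersal,
  aestivation, migration and `alpha0` all zero; a settlement is persistent
  if some life stage is present at every year-end, majority-voted over
  three replicates.
* **Rainy-season occupancy** is the presence of at least one active adult
  (aestivators excluded) on 19 October (day 292), and the headline statistic
  is the fraction of settlements unoccupied on that day, observed per output
  year and replicate.
* **Resurgence date** at a site is the first day of year at or after day
  140 on which the active-female count reaches 10% of that site-year's
  peak; site-years whose peak stays below 20 females count as uncolonised.
  The threshold is deliberately scale-free: multiplying a series by a
  constant leaves the date unchanged.
* **Correlation measure** for the occupancy correlates is the point-biserial
  correlation (Pearson correlation of the binary colonised indicator with
  distance-to-persistent-site, and with the settlement count within 10 km),
  over non-persistent settlements; "colonised" means occupied in at least
  half of the output year-replicates.
* **Distances** are haversine on a 6371 km sphere — at a 1000 km regional
  extent the difference from an ellipsoidal geodesic stays under ~0.6%,
  and it avoids a projection dependency. Settlements map to rainfall cells
  by containing-cell lookup; no interpolation. A settlement pair at exactly
  `L_D` gets zero kernel weight (open-ball support).
* **Degenerate inputs**: `alpha = 0` with juveniles present gives
  `p_s = 0`; an empty settlement is an absorbing state (no spontaneous
  generation), and whole-metapopulation extinction ends a replicate early
  with the remaining records zero.
* **Reproducibility**: every stochastic entry point seeds R's
  Mersenne-Twister explicitly (inversion normals, rejection sampling);
  replicate seeds derive from the master seed, and the per-settlement
  `alpha0` draw is redrawn per replicate, so replicate variation includes
  the cryptic-habitat lottery rather than conditioning on one realisation.

## Design choices made where the design was open

* The lognormal `alpha0` moments are interpreted on the natural scale
  (converted internally to log-scale parameters), because they are stated
  as the mean and variance of the across-settlement distribution.
* The migration wedge is the 90-degree sector centred on the SW (or NE)
  bearing, extending to the region edge, with destinations uniform within
  it; sites exactly on a wedge edge (due north, due east) belong to neither
  wedge. The wedge rule sits behind `build_wedges()` so half-plane or
  corridor alternatives can be swapped in.
* `mu_J` multiplies the *daily* density-dependent survival term, so
  density-independent survival over development is `(1 - mu_J)^T_L`; a
  per-development reading would simply rescale the parameter.
* Dispersal applies to all adult classes; aestivation and migration to
  mated females only. Virgin females neither aestivate nor migrate.
* Under the 30-day longevity cap, adult age classes are tracked only when
  the cap is enabled (the default state stays small); an aestivating
  female's dormancy resets her age class on emergence.
* Aestivation survival is drawn at entry; the emergence day is uniform on
  integer days of the emergence window.
* Dispersal precedes migration within a day, so migrants are drawn from
  post-dispersal residents; a migrating female relocates instantaneously.

## Known limitations

Temperature- and humidity-dependent vital rates, larval-site flushing by
heavy rain, downstream pooling of drying rivers, species-specific
(*gambiae* / *coluzzii* / *arabiensis*) parameterisations and malaria
transmission are all out of scope. The carrying-capacity constants are
placeholders pending calibration against field population estimates, so
absolute occupancy percentages produced on synthetic landscapes are not
comparable with the field; the package's claims are about mechanism
contrasts (dispersal in, aestivation in, migration in, cryptic habitat in)
under matched conditions.

## A worked example

```{r example, eval = FALSE}
ls <- generate_landscape(reference_scenarios()[["arid-north"]])
cf <- simulation_config(ls, years = 3, burn_in_years = 2, replicates = 10,
                        seed = 1, record = "summary")
persistent <- classify_persistent(cf)
runs <- lapply(c(0, 0.005, 0.034, 0.1), function(d) {
  run_simulation(simulation_config(ls, years = 3, burn_in_years = 2,
                                   replicates = 10, seed = 1,
                                   movement = movement_params(d = d),
                                   record = "summary"))
})
names(runs) <- c(0, 0.005, 0.034, 0.1)
unoccupied_fraction_curve(runs, values = c(0, 0.005, 0.034, 0.1))$summary
```

The same sweep, the aestivation/migration contrasts and the dry-season
dynamics signatures are exercised end to end, with their numerical
assertions, in `tests/testthat/test-acceptance.R`.
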