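Package: sahelsim
Title: Stochastic Metapopulation Simulation of Malaria Vector Mosquitoes on
    Settlement Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based, spatially explicit model of Anopheles
    gambiae s.l. population dynamics on a network of human settlements in
    seasonally arid West Africa. Local carrying capacity is driven by weekly
    rainfall and by the length of perennial and intermittent water courses
    near each settlement; daily stochastic demography covers larval
    competition, emergence, mating, oviposition and adult mortality. Adults
    disperse among neighbouring settlements, and three dry-season survival
    mechanisms can be switched on: aestivation of mated females, seasonal
    wind-aligned long-distance migration, and cryptic small permanent larval
    sites. Includes a synthetic-landscape generator emulating the study
    region, persistence/occupancy classification, and summary analyses of
    the colonisation-extinction dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
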