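Package: peatstsm
Title: State-and-Transition Carbon Stock-Flow Simulation for Forested Peatlands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit state-and-transition simulation model coupled
    to an annual carbon stock-flow (gain-loss) model for forested peatland
    landscapes, developed around the Great Dismal Swamp ecosystem. Tracks eight
    carbon pools per 1-ha cell (live leaf, live wood, live root, leaf litter,
    deadwood, dead root, and a two-layer acrotelm/catotelm peat column),
    simulates alternative succession with age gating and neighbourhood
    adjacency, hurricane blow-down, deadwood salvage, and severity-classed
    wildfire with peat combustion, and reports annual net ecosystem production
    (NEP) and net ecosystem carbon balance (NECB). Includes a 300-year
    cold-start spin-up calibration producing age-biomass growth curves, a
    biomass-to-age lookup, and a seeded synthetic landscape generator with
    contiguous fire perimeters and controlled overlap.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
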