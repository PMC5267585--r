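---
title: "A coupled state-and-transition / carbon stock-flow model for a forested peatland"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled state-and-transition / carbon stock-flow model for a forested peatland}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peatstsm` simulates the carbon balance of a forested peatland landscape by
coupling two layers that run on the same annual clock:

1. a **state-and-transition simulation** (a non-stationary Markov chain over
   discrete land-cover states on a grid of 1-ha cells), and
2. a **stock-flow model** that moves carbon between eight per-cell pools
   under the IPCC gain-loss convention.

This vignette documents the model structure, the parameters and their
defaults, the numerical choices, what the synthetic landscape generator does
and does not emulate, and the design decisions taken where the published
description of the system leaves the implementation open.

## State variables

Each active cell carries:

* a **state class** — Atlantic white cedar, cypress-gum, maple-gum and pond
  pine are the modelled forest communities; marsh and open water are
  non-forested states with passive peat pools; upland pine is carried but
  inert (no transitions, no flows);
* a **stratum** — Wet or Dry. The Dry stratum marks the drought-vulnerable
  zone where repeat fires become catastrophic. No Wet/Dry conversion
  dynamics are simulated: the pathways exist conceptually (re-wetting by
  restoration, drying by drainage or drought) but no annual rates are
  available, so the stratum is constant over a run;
* a **stand age** (forested classes only), incremented each year and reset
  by stand-replacing disturbance (high-severity fire, repeat-catastrophic
  fire, hurricane, replanting);
* eight **carbon pools** in t C/ha: live leaf, live wood, live root, leaf
  litter, deadwood, dead root, upper peat (acrotelm, 0–40 cm) and deep peat
  (catotelm, 41–100 cm), plus the remaining depth (cm) of each peat layer.

The peat pools are initialized from a standardized 100-cm column at

$$\rho = \mathrm{BD}\times\mathrm{OM}\times\mathrm{C}\times 100
       = 0.16 \times 0.95 \times 0.59 \times 100 = 8.968
  \ \mathrm{t\,C\,ha^{-1}\,cm^{-1}},$$

giving 358.7 t C/ha for the acrotelm and 538.1 t C/ha for the catotelm
(the source tables print 358.40/537.60 from the rounded 8.96). Soil
chemistry (`soil_params()`) is configurable; the defaults are the site
means of 26 soil cores.

## Annual carbon flows

All flows of a year are computed *simultaneously* from start-of-year stocks
(an explicit forward step with Δt = 1 yr), then applied. For a forested cell
of species $s$:

* **Growth** — the constant species NPP $P_s$ (t C/ha/yr) enters the live
  pools as $f^{leaf}_s P_s$, $f^{wood}_s P_s$, $f^{root}_s P_s$ with
  $f^{leaf}+f^{wood}+f^{root}=1$ (asserted at parameter load).
* **Litterfall / mortality** — proportional multipliers of the live
  from-stocks (e.g. wood mortality 0.021/yr for cedar ≈ the 3%/1.5%
  live-wood mortality convention after calibration).
* **Humification** — multipliers of the detritus from-stocks into the upper
  peat.
* **Detritus emission** — multipliers of the detritus from-stocks to the
  atmosphere. Together with the upper-peat emission these constitute
  heterotrophic respiration $R_h$.
* **Peat accumulation** — an *absolute* species rate (t C/ha/yr) from upper
  to deep peat: 0.36 (cedar), 0.14 (cypress-gum), 0.12 (maple-gum), 0.17
  (pond pine). This is the only long-term sink.
* **Upper-peat emission** — the acrotelm is modelled at steady state:
  emission $= \max(0,\ \text{humification inflow} - \text{accumulation})$,
  so the acrotelm stock is constant whenever humification at least covers
  the accumulation transfer.

The parameter tables also contain proportional multipliers for the two peat
flows (e.g. 0.022 and 0.0012 of the acrotelm stock for cedar). These rows
are numerically inconsistent with the calibrated flow densities and the
species accumulation rates (0.022 × 358.4 = 7.89 ≠ 7.65;
0.0012 × 358.4 = 0.43 ≠ 0.36), and which form was used internally by the
original modellers cannot be determined from the published description.
`step_flows(..., peat_mode = "multiplier")` therefore exposes the multiplier
form as a sensitivity mode, while the default mode uses the steady-state
rule plus the absolute accumulation rates, which is the form the published
arithmetic (e.g. the 1740-year re-accumulation horizon) is built on.

A load-time integrity check (`check_flow_calibration()`) verifies for every
biomass flow of every species that
*multiplier × mature from-stock = literature density + calibration delta*
within 0.01 t C/ha/yr, which pins the transcription of all three parameter
tables against each other.

**Mass conservation.** Every operation returns flux records; for any step,
Δ(total ecosystem C) = inflows from atmosphere − outflows to atmosphere −
outflows to harvested wood products, to 1e-9 t C/ha (`mass_balance()`).
Outflows are proportionally rescaled if they would overdraw a from-stock, so
no pool ever goes negative; in practice the only pool that can bind is a
freshly-burned or cold-started acrotelm.

## Spin-up calibration and the biomass-to-age lookup

Mature-stand stock densities describe equilibrium stands only, so
age-structured initial conditions are produced by a 300-year **cold-start
spin-up** per species (`run_spinup()`): all pools start at zero and the
annual step is iterated with constant NPP. Because each live pool is then a
linear first-order compartment, live wood follows the discrete closed form

$$B(t) = \frac{I}{m}\left(1 - (1-m)^t\right),\quad I = f^{wood}_s P_s,$$

which the test suite uses as an exact oracle (agreement to 1e-9 t C/ha).
The curves are strictly concave with no inflection — constant NPP cannot
produce the sigmoidal juvenile phase of real stands — and saturate at
$I/m$. "Live tree" biomass is defined as live leaf + live wood (roots
excluded); this aggregation best matches the published calibration
waypoints, and is configurable via `live_tree_biomass(include_roots=)`.

`find_equilibrium()` returns the smallest age whose annual relative
live-tree increase drops below `tol = 1e-3`/yr. The tolerance is a package
choice (none is published); note that for a single pool the stopping rule
leaves the curve a factor $\mathrm{tol}/m$ below its asymptote (~5% for
wood), so the equilibrium *biomass* is read from the curve, not from the
asymptote. `build_age_lookup()` inverts the increasing segment of the
curve; biomass above the curve maximum maps to the equilibrium age, and
`biomass_to_age()` returns the smallest age whose curve value reaches the
input (with a 1e-9 guard against float noise). `rollback_ages()` uses these
curves to re-derive stocks at rolled-back ages and to reconstruct the
fire-scar region as cedar at age 100, the average mature cedar age.

## The transition layer

* **Alternative succession**: recently disturbed cedar and pond pine stands
  (age ≤ 5) convert to maple-gum with annual probabilities 0.80/0.50 (Dry)
  and 0.04/0.01 (Wet), scaled by the proportion of the 8 neighbours already
  in maple-gum (edge cells normalize by their in-grid neighbour count — a
  package choice avoiding edge bias). Adjacency is refreshed every 5
  simulated years, starting at year 0.
* **Area targets**: known events are prescribed as (year, mask, area);
  exactly min(target, eligible) cells transition, drawn uniformly without
  replacement when the mask over-covers the target (the published
  description is silent on within-mask selection). Event groups within a
  year run in random order.
* **Fire severity**: burned cells draw high/med/low labels at proportions
  0.163/0.409/0.428; only high severity resets age. Cells without an
  event-specific consumption spec burn with per-severity default
  consumption — low: 50% of leaf litter; med: all leaf litter + 50% of
  deadwood; high: 80% of the four above-ground pools, no peat. These
  defaults are a package reconstruction (published consumption figures
  exist only for the two catastrophic fires) and are fully configurable.
* **Repeat-catastrophic fire**: a cell burning again within 5 years
  (strictly: gap in the open interval (0, 5)) in the Dry stratum. "Patch"
  is interpreted per cell. Such cells receive the event's catastrophic
  consumption (remaining above-ground biomass, 50 cm of peat, live and dead
  roots), reset age, and convert to marsh, keeping any residual pool mass
  on the books so the ledger stays conservative. Whether med/low severity
  fires cause state change was left unspecified; the package defaults to no
  class change below high severity.

The within-year operation order is: targeted transitions → probabilistic
transitions → stock-flow step → age increment. Placing flows after
transitions makes fire consumption act on current-year stocks.

## The 1985–2015 reconstruction

The default schedule (`default_schedule()`) encodes: Hurricane Isabel 2003
(625 ha of cedar blown down, live pools transferred to dead pools, age
reset); deadwood salvage + cedar replanting of 316 ha spread over 2004–2007
(79 ha/yr, deadwood to the harvested-wood-products pool); the South One
fire 2008 (2400 ha, 80% of the above-ground pools + 20 cm of peat); the
Lateral West fire 2011 (2500 ha, 85% overlapping the South One perimeter);
and four background fires (1989/1995/2001/2014, 250–400 ha, severity-based
consumption) standing in for the remaining historical fire record.

Reconstruction choices to note:

* The published account gives the South One area as both 2400 and
  "approximately 2500" ha; 2400 is used.
* The Lateral West catastrophic consumption (remaining AGB + 50 cm peat +
  roots) applies to the *overlap* with the South One burn — exactly the
  repeat-catastrophic cells — matching the description of the second fire
  consuming the remaining biomass "in the overlapping burn area"; the
  non-overlapping 15% burns with severity-default consumption. The 0.85
  overlap fraction is derived so that the overlap area × 50 cm × 8.968
  reproduces the published below-ground loss of that fire; it is a
  documented configuration value, not ground truth.
* The hurricane footprint is placed inside the overlap (its salvage block
  inside it), so the post-hurricane fuel loads burn in the South One fire —
  the mechanism behind that fire's larger above-ground emission.

The annual ledger aggregates Growth, $R_h$, fire emissions (split
above-/below-ground per event), management removals, NEP, NECB and total
stocks in Tg C (1-ha cells make t C/ha sum directly to t C). Fire emissions
are never double-counted in $R_h$. `summarize_fire_events()` converts each
event's peat combustion to a soil-elevation-loss equivalent,
$\mathrm{BGB}_{peat} / (\rho \times \text{burned peat area}) / 100$ m.
`re_amass_time()` divides a burned peat column's carbon by a long-term
accumulation rate and rounds to the nearest decade.

## The synthetic landscape generator

No spatial inputs are distributable, so `generate_landscape()` builds a
seeded stand-in: class patches grown from random nuclei by frontier
expansion (~600-ha patches) until each class hits its target cell count
exactly (composition defaults: cedar 3%, cypress-gum 12%, maple-gum 61%,
pond pine 15%, marsh 6%, open water 3% of 54,000 ha); a contiguous Dry
region grown around the fire-scar area to 10% of the landscape; and
forested ages drawn uniformly on [20, 80] years. The generated ages are
used directly as the 1985 initial structure (the scar region overridden to
cedar at age 100): generating the simulation-start age structure directly
is cleaner than emulating an unavailable present-day age map and rolling it
back, and the [20, 80] range represents a landscape recovering from the
logging era that preceded refuge establishment. Fire perimeters are grown
8-connected with exact cell counts and exact overlap counts
(`generate_fire_perimeter()`), verified by flood fill in the tests.

What the generator does *not* emulate: the true patch geometry, the real
age map and strata (produced by interactive mapping), spatially variable
peat depth, and the real fire-perimeter shapes. Full-landscape totals from
synthetic runs are therefore approximate by construction, and the test
suite treats them as property checks (sink-to-source reversal, ledger
closure, event-level emission ordering) rather than map-accurate
reproductions; the two-fire emission totals are the exception, since they
are dominated by the prescribed consumption specs rather than the map.

## Problem sizes and runtime

The reference configuration uses the full 54,000-cell grid for 30 annual
steps, 300-year spin-ups, and single-cell landscapes for the flow-level
unit tests; the generator tests use a 3,000-ha configuration. A complete
reference run (generation + simulation) takes a few seconds on one CPU, and
the whole test suite under a minute.

## Known limitations

* No CH₄ or N₂O accounting — carbon only, so the climate implications of
  re-wetting trade-offs are outside scope.
* No hydrologic model: the water table enters only through the static
  Wet/Dry strata and the acrotelm/catotelm split.
* No temperature or moisture modifiers on decomposition; multipliers are
  stationary.
* Constant NPP by species — no age-dependent productivity, hence no
  sigmoidal growth.
* Uniform 100-cm initial peat depth; real profiles range ~0.3–3 m.
* Raster I/O covers the ESRI ASCII grid and the CSV cell table; the
  geospatial layer is deliberately thin (no CRS handling beyond
  pass-through).
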