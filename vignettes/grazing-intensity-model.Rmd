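---
title: "Modelling the spatial distribution of grazing intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the spatial distribution of grazing intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazemap)
library(dplyr)
```

## The problem

Pasture is the single largest agricultural land use, yet its extent and the
intensity with which it is used are poorly known: grazing — especially
low-intensity grazing — leaves almost no remotely detectable signature, and
livestock statistics are reported for administrative units, not pixels.
`grazemap` implements an energy-budget allocation model for rangeland
systems in which herds are tethered to settlements (the post-Soviet steppe
being the archetype): it converts net primary productivity (NPP) into a map
of grazeable energy, converts livestock statistics into settlement-level
energy demand, and distributes that demand onto the map with a competitive
search algorithm that mimics settlement-based optimal foraging. The result
is a per-pixel *grazing intensity* — the fraction of produced biomass
energy consumed — from which utilized pasture extent, sustainable stocking
margins and production-expansion potentials follow.

## Supply: from NPP to grazeable energy

Each pixel's annual total NPP $P$ (gC/m²/yr) is converted to dry matter
with a carbon fraction of 0.47 gC/gDM and then to metabolisable energy.
On grassland (bare soils included — they are grazed, merely unproductive):

$$E = \frac{P}{0.47}\cdot \frac{8.6}{1000} \quad \text{MJ/m}^2,$$

with 8.6 MJ/kgDM the herbage energy content typical of dry steppe. On
cropland only post-harvest residues are grazeable. With a harvest index of
0.48 (wheat reference) and 90% of wheat biomass aboveground at harvest,

$$E = \frac{P}{0.47}\cdot 0.90\,(1-0.48)\, \frac{6.0}{1000} \quad \text{MJ/m}^2,$$

using the lower residue energy content of 6 MJ/kgDM. The composition
`total DM × aboveground fraction × (1 − harvest index)` is the only
arrangement of the three published factors consistent with the harvest
index being defined on *aboveground* biomass. Forest, water, ice,
artificial surfaces and strictly protected preserves are masked out.
Missing NPP on grazeable cover is treated as zero energy with a warning
rather than an error, which keeps maps with ragged edges usable.

Only part of total NPP can be consumed sustainably: about 77% of steppe NPP
is aboveground, and roughly 40% of the aboveground production can be
removed without degrading regrowth, giving a maximum sustainable off-take
near 30% of total NPP (`max_sustainable_offtake()` returns the exact
product, 0.308).

## Demand: from district statistics to settlement energy

District herd counts per species (goats are merged into sheep throughout)
and farm type are split into age/function groups using province-level
census compositions — the only scale at which herd structure is reported —
so that group counts sum back to the district totals exactly. Each group
carries an annual metabolisable-energy requirement (MJ/head/yr) that
differs by farm type, since enterprises target higher growth rates than
households. Fodder production is converted to energy through per-type
feed-unit ratios and assigned to species by province consumption shares;
fodder destined for pigs and poultry simply never reaches the grazers.
Fodder trade between districts is ignored — its magnitude is unknown and
no defensible allocation exists.

Grazing demand is total demand minus fodder energy, floored at zero
(surplus fodder cannot create negative grazing; the handful of clamped
cells are logged). The *grazing gap* — grazing demand over total demand —
is the headline diagnostic; steppe systems typically sit near 0.7–0.8.

District demand is split across settlements by weights
$w_i = \text{pop}_i \times f(\text{pop}_i)$, where $f$ is the
piecewise-linear fraction of residents keeping livestock: 0.95 up to 1,000
residents, 0.80 at 5,000, 0.30 at 10,000, 0.10 at 50,000 and 0.005 at one
million, constant beyond. Between 0 and 1,000 the function is flat at 0.95
(no interior knot exists in that range). Conservation is exact at both
disaggregation steps and is tested to a relative tolerance of 1e-9.

## Allocation: competitive radius-expanding greedy search

Demand is distributed in nine groups, strictly ordered by mobility:
household sheep+goats, household cattle, private-farm sheep+goats,
private-farm cattle, enterprise sheep+goats, enterprise cattle, then
horses of all three farm types. Base search radii are 2 km
(household/private-farm cattle and small stock), 5 km (enterprise cattle
and small stock) and 10 km (horses, which remain on pasture overnight).

Within a group every settlement with unmet demand searches the cumulative
disk of radius $k\,r$, $k = 1, 2, 3, \dots$. Pixel preference is energy
density first, then proximity, then row-major index (a pure tie-break).
Claims are exclusive for the entire nine-group run; a claimed pixel yields
`off-take rate × pixel energy`, except the final pixel a settlement needs,
which is claimed whole but consumes only the residual demand — this
*partial final pixel* is what makes energy conservation exact rather than
approximate. The ring index advances only when no participating settlement
can claim, and a settlement drops out (flagged unmet, with a warning) only
once the entire landscape within its reach is exhausted.

The published description of the algorithm says the distribution is
performed "simultaneously" across settlements to allow fair competition,
but specifies neither a turn order nor a conflict-resolution rule. We
operationalise simultaneity as one-pixel-per-turn round-robin in ascending
settlement id within each ring: it is deterministic, it interleaves
competitors at the finest possible granularity, and on contested pixels it
reduces to a fixed, documented tie-break. Whether the original
implementation allowed multiple pixels per turn is not decidable from the
text; only the round-robin interpretation is implemented. The ranking key
is energy density rather than raw NPP: on grassland the two orderings
coincide (the conversion is a positive scalar), and on cropland the energy
map already embeds the residue arithmetic of the merged supply map.

The engine is written in C++ (per-settlement lazy annulus loading into
priority queues, with stale-entry discarding); an independent brute-force
oracle that rescans the whole grid every turn is kept in the test suite,
and the two are compared pixel-for-pixel on randomized instances up to
8×8 cells, 3 settlements and 3 groups, with deliberate energy ties.

## Off-take calibration

A uniform off-take rate is unrealistic: the same herd removes a larger
share of a poor pasture than of a rich one. The model is therefore run
under eleven uniform rates (10% to 60% in 5% steps) and each district is
assigned the *lowest* rate at which the median maximum grazing distance of
household cattle — the most distance-restricted group — falls strictly
below 10 km. Districts with no household cattle fall back to household
sheep+goats; districts with neither have no grazing livestock and receive
no rate (their settlements use a configurable default, 0.10, in the final
run). Three choices the published method leaves open are resolved as
follows and are configurable: settlements with zero reference-group demand
are excluded from the district median (the statistic describes settlements
that actually graze); districts that fail even at 60% receive the 60%
ceiling with provenance `"ceiling"`; and the final run lets every
settlement carry its district rate wherever it grazes, so rate boundaries
follow herds rather than administrative lines. The calibrated map is the
model's analogue of an observed grazing-intensity distribution.

## Production scenarios

Baseline productivity divides reported meat and milk production by the
model's utilized area per species and farm type; cattle area is pro-rated
by the dairy herd fraction (0.40/0.50/0.85 for enterprises, private farms
and households) before computing milk yields. Expansion scenarios treat
unclaimed grazeable pixels within 10 km (conservative) or 20 km
(optimistic) of any settlement as available. Under business-as-usual the
additional energy values each pixel at its district's calibrated rate;
under the maximum-sustainable scenario the allocation is re-run at a
uniform 30% and the then-unclaimed pixels are valued at 30%. A fresh
re-run — not a rescaling of the calibrated map — is used because higher
rates change *which* pixels are claimed, not just how much each yields.

Additional energy is converted to beef or milk (either/or uses of the same
land) by two labelled paths reported side by side: `area`
(area × baseline per-km² productivity of enterprise cattle) and `energy`
(energy ÷ per-head demand × per-head product). Two paths are exposed
because the published chain from additional area and energy to additional
production is not reconstructible from printed values alone — the printed
per-area yields give a different order of magnitude than the printed
additional production, suggesting unrounded intermediates. When enterprise
cattle have no grazing footprint at all the area path is undefined and is
reported as `NA`.

## The synthetic landscape

No deposited inputs exist, so the generator is first-class, tested code.
It emulates the structure the model assumes: a northeast–southwest NPP
gradient (250 to 60 gC/m²/yr by default, the span of dry-steppe
climatologies) under multiplicative lognormal noise (σ = 0.25,
mean-corrected); cropland placed in 8-cell blocks (fields are contiguous,
not salt-and-pepper) with the remaining cover drawn iid; a rectangular
district partition grouped into provinces; half-clustered settlements with
lognormal populations (median 1,000, σ_log = 1.2 — heavy-tailed, and
sized so the default country's population density matches semi-arid
rangeland reality); livestock at 0.36 cattle, 1.05 sheep+goats and 0.12
horses per resident with 60/25/15% farm-type shares; and fodder sized to
cover ~22% of herd demand, yielding a grazing gap near 0.78. Everything
flows from one seed through per-component sub-streams, so adding a
component does not perturb the others and regeneration is bit-identical.

The default country (400 × 400 cells of 500 m — about 40,000 km² — 12
districts, 150 settlements) runs the full pipeline, including the
eleven-rate calibration sweep, in well under a minute; these sizes were
chosen so that end-to-end experiments iterate in seconds while remaining
two orders of magnitude above the scales where discretisation artefacts
are visible.

What the generator does *not* emulate: riparian corridors and other
fine-scale NPP structure, the co-location of settlements with
high-productivity land (synthetic settlements are placed independently of
NPP, so the near/far productivity contrast observed around real
settlements does not arise), unreported household hay-cutting, and
inter-district fodder trade. Passing tests on synthetic landscapes
therefore validate the *mechanics* — conservation, exclusivity,
monotonicity, calibration recovery — not the realism of any particular
national map.

`make_recovery_fixture()` closes the loop on calibration: it bisects a
demand scale until the reference-group median distance brackets the 10-km
criterion exactly at a requested grid rate (verified by running the two
adjacent sweeps), so that calibration must recover the planted rate. The
test suite requires ≥95% recovery across fixtures.

## Numerical choices and edge cases

* Energies are double-precision MJ throughout; PJ appear only in reports.
  Distances are metres internally, kilometres at the API surface.
* Pixel membership in a ring uses centre-to-point Euclidean distance
  ≤ $k\,r$ (cumulative disks, not half-open annuli); the first disk
  includes the settlement's own pixel (distance 0).
* Zero-energy pixels are never claimable: claiming them could not reduce
  demand and would stall termination.
* Ties in energy density are real (categorical NPP plateaus survive the
  linear conversion) and are broken by distance, then row-major index.
* Fodder above demand clamps grazing demand at zero; the gap is defined
  as 0 when total demand is 0.
* The 10-km criterion uses strict `<`, as specified.
* Validation errors carry classed conditions (`grazemap_error_geometry`,
  `_validation`, `_config`, `_fixture`) so callers can branch on them.

## File formats

Rasters are exchanged as ESRI ASCII grids (`.asc`) — a plain-text,
GIS-interoperable format — with cover classes encoded by the
`cover_classes()` legend; settlements as GeoJSON points or CSV; statistics
and reports as CSV; configuration as YAML; run manifests (input hashes,
versions, headline totals) as JSON. Coordinates must be projected metres;
resampling helpers (`resample_raster()`) bring mixed-resolution inputs
onto the common grid, nearest-neighbour for categorical and block means
for continuous fields.

## Known limitations

Water points and seasonal migration are not modelled (no usable data
exists at country scale for the archetype system); herd movement within
the year is collapsed into an annual energy budget; settlements of equal
size within a district receive equal livestock, which understates the
concentration of enterprise herds in particular villages; and the greedy
search is a behavioural approximation, not an optimisation — its value is
that it is deterministic, conservative and testable.
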