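---
title: "Standardizing bottom-trawl surveys and flagging unstable footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing bottom-trawl surveys and flagging unstable footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlr)
```

## The problem

A scientific bottom-trawl survey samples a region once or twice a year with
standardized gear, recording abundance and/or weight per taxon per haul. Two
artefacts frustrate spatio-temporal analysis of such series. First, the
*footprint drifts*: weather, funding and vessel availability move the set of
locations actually sampled from year to year, so apparent community change
can be pure geography. Second, *identification drifts*: surveys change the
rank or name under which they record difficult taxa (e.g. a species pair
collapsed to its genus once the field distinction is judged unreliable), so
one biological population appears as two names that switch over mid-series.

`trawlr` standardizes a haul-level table into comparable units and attaches
two flag families — per-haul footprint flags and per-taxon temporal
consistency flags — that let the analyst trim the data to a stable core
rather than silently analyse the artefacts.

## Standardization pipeline

`read_survey_table()` reads one row per taxon per haul in a canonical
snake_case dialect (`survey_dialect()`); foreign column names are translated
by a rename map, because source agencies do not share a file dialect.
Unparseable numeric cells become absent with a logged warning rather than
failing the read: a single corrupt cell should cost one value, not a survey.

`apply_quality_filters()` enforces the mandatory-field rules. A usable haul
has geolocation (both coordinates, in bounds — depth is deliberately *not*
mandatory, since it is a covariate rather than a sampling requirement), a
full calendar date, a gear code, and at least one effort proxy (haul
duration or swept area; either suffices). Hauls flagged invalid by the
source survey and non-otter-trawl hauls are dropped; beam trawls sample with
different catchability and are out of scope beyond flag-and-drop. Negative
abundance or weight is an integrity violation and removes the record; null
(zero) catches are valid observations and are kept. Hauls whose catch
records carry neither abundance nor weight are dropped at the dataset level;
because this test depends on record content, it is re-evaluated whenever the
filter runs (before or after harmonization), and the filter is idempotent.

### Taxonomy

Harmonization works against a *local backbone snapshot* (AphiaID-like
identifiers, statuses, accepted targets, classes, optional length–weight
coefficients), pinned by md5 in the processing log. Resolution order in
`harmonize_name()`:

1. an alias entry scoped to the survey unit, then a global (`"*"`) alias —
   aliases encode curated survey-specific overrides such as recording an
   unreliable species pair at genus rank;
2. an exact identifier match;
3. an exact name match, case-insensitive and whitespace-normalized.

Synonyms resolve to their accepted entry in one step (a backbone validity
invariant). When identifier and name disagree, the identifier wins and the
conflict is logged: codes are machine-assigned, names are typed. There is
*no* fuzzy matching: unmatched names are surfaced in a curation report and
removed by the class filter, never silently kept or guessed — automatic
fuzzy assignment is exactly the kind of silent error the flags exist to
catch. The class allowlist defaults to the five fish classes
(`fish_classes()`); invertebrates are dropped because surveys do not sample
them consistently.

`aggregate_per_taxon_haul()` merges records that resolve to the same
accepted taxon within a haul, summing absent-aware (the sum is absent only
when every term is) and concatenating the contributing verbatim names for
provenance. Unmatched records are keyed by verbatim name so distinct
unmatched names never collapse.

### Effort and rates

Swept area (km²) is towed distance × gear opening, with distance
reconstructed as speed × duration when unrecorded (knots → km/h via 1.852
exactly). The gear opening means wing spread where both wing and door
spread exist, since wing spread bounds the catching width; a survey-wide
standardized opening can substitute when the haul-level value is missing.
When swept area still cannot be derived, `fit_swept_area_model()` fits a
single OLS on the largest predictor subset available in ≥ 80 % of training
rows (candidates: duration, depth, sweep length, country, vessel; main
effects only — the alternative, per-haul best subsets, would make imputed
values incomparable across hauls). It requires ≥ 10 complete cases and more
rows than parameters, drops single-valued predictors, and records n and R².
`impute_swept_area()` fills only absent values, floors non-positive
predictions at the smallest observed area with a warning, and leaves hauls
without predictors (or with unseen factor levels) absent and logged.

Weights missing from abundance-only surveys are reconstructed from
abundance-at-length with *w = a·lᵇ* (coefficients in the backbone; grams for
cm, converted to kg). Rates are CPUE = catch / hours and CPUA = catch / km²,
absent whenever numerator or denominator is absent; the inversion identities
(rate × effort = catch) are enforced by test to 1e-12 relative tolerance.

## Temporal taxonomic flags

Per survey unit, `build_presence_series()` computes a per-taxon boolean
sequence over the years the unit actually sampled; skipping unsampled years
prevents artificial transitions across gaps. Presence requires a strictly
positive abundance or weight — a null catch is an absence. `flag_taxa()`
flags a taxon when presence fraction < 0.95 **and** transition count < 4,
both strict. The conjunction is intentional: low presence with few
transitions is the block structure left by a naming switch, while low
presence with many transitions is an ordinarily rare species. Both
statistics are returned so users can re-derive a disjunctive or re-thresholded
rule. Units with fewer than two sampled years return `NA` flags with a
warning. The rule is verified against brute-force evaluation over all 8,190
presence vectors of length ≤ 12.

## Footprint flags

### Hexagonal cell-year completeness

Hauls are binned into hexagonal cells whose area equals the aperture-3
icosahedral mean, Earth surface / (10·3ʳ + 2): ~23,320 km² at resolution 7
and ~7,770 km² at resolution 8. The default backend projects coordinates to
a Lambert azimuthal equal-area plane centred on the survey-unit centroid and
tiles it with regular pointy-top hexagons of exactly that area. Equal-area
projection on the sphere is exact, and regional survey domains are small
enough that planar tessellation preserves the method's intent; the
assignment function is a pluggable argument of `flag_hauls_hex()`, so a true
spherical discrete global grid can be swapped in without touching the flag
logic.

`select_core()` then searches for the largest consistently sampled core.
Cells are ordered by the number of years they were sampled and years by the
number of cells, descending, with lexicographic tie-breaks for determinism;
every top-*i* × top-*j* rectangle is scored and the one maximizing the
retained cell-year count *i·j* subject to the missing budget (0 % or 2 %)
wins, ties preferring more years, then more cells. Two deliberate choices:

* **The sorted-rectangle family.** The unrestricted largest complete
  submatrix problem is NP-hard, and ordering both axes by marginal coverage
  is exactly how the diagnostic figures of this method family are drawn
  (well-sampled cells and years in the top-right corner). Within this family
  the search is exhaustive and exactly solvable, and the implementation is
  tested against an independent brute-force search on random matrices up to
  12×12 at both budgets.
* **The 2 % denominator.** "2 % of all grid cell-years" can be read against
  the candidate rectangle or against the survey unit's full matrix. The
  rectangle reading is scale-free (a budget that does not loosen as the
  full matrix grows) and matches the threshold lines of the diagnostic
  figure, so it is the default; the matrix reading is available via
  `denominator = "matrix"`.

At threshold 0 the retained rectangle is complete by hard assertion. A haul
is flagged when its cell or its year is outside the retained sets; the four
settings {7, 8} × {0 %, 2 %} give four flags. The flagged *count* at 0 % is
never below the count at 2 % (feasible sets nest), but the flagged *sets*
need not nest, because the two optima may retain different rectangles.

### BioTIME-style rule

The fifth flag uses a 5×5 rectangular grid whose cell size is one fifth of
the survey's latitude and longitude range (half-open bins, maximum edge
closed, degenerate extents collapse to one cell). A haul is flagged when its
cell-year has fewer than 4 hauls (guarding against sampling noise from a
few events; haul events are counted, not distinct coordinates), or when its
cell has fewer than 10 years meeting that rule — ten years being the
conventional minimum for temporal ecological analysis. Note the second
stage counts only qualifying years, not all sampled years.

## The synthetic world

`generate_survey()` builds datasets with known truth so every stage has a
recovery test without downloads. The stated world: 12 core stations sampled
every year and 8 transient stations sampled with probability 0.3 per year,
over 20 years, 4 hauls per station-year (the minimum that can satisfy the
BioTIME cell-year rule), six species with occupancies 0.4–0.95 and lognormal
densities, one genus-level protocol switch halfway through the series, and
configurable effort missingness. Stations sit on a 3° × 4.5° grid (~300 km
spacing) so each occupies its own hexagonal cell at resolutions 7 and 8, and
hauls scatter within ±0.02° (~2 km) of their station, emulating a
fixed-station design in which the vessel relocates the same station within a
few km each year. The tight scatter is a *requirement of the generator's own
contract*, not a tuning knob: its ground truth labels whole stations as core
or transient, which is only meaningful if a station lies within one grid
cell; wider scatter makes stations straddle cell boundaries and the truth
labels ill-defined. Catch counts may be fractional (density × swept area),
as in real raised subsampled catches; every haul keeps at least one catch
record so a complete-effort world passes the quality filters untouched.

Randomness is split into per-stage sub-streams derived from the master seed,
so changing the species pool does not move haul positions. What the
generator does *not* emulate — and what a green recovery test therefore does
not establish — includes gradual footprint drift (transience is binary per
station), depth/bathymetry structure, gear selectivity and catchability,
spatial autocorrelation of abundance within cells, and partially overlapping
survey units.

## Numerical conventions and degenerate inputs

* Units: km, km², minutes for duration but hours for CPUE, kg, knots
  converted by exactly 1.852; all declared in the column documentation.
* Missing values are `NA` end to end; empty strings on disk.
* `select_core` uses an absolute 1e-9 slack on the budget comparison so a
  rectangle with exactly 2 % missing is feasible despite floating-point
  division; tie-breaks (more years, then more cells, after lexicographic
  axis ordering) make the optimum unique and order-independent.
* Empty incidence matrices, zero-length presence sequences, non-positive
  effort inputs and invalid simulation configs raise classed errors
  (`trawlr_domain_error`, `trawlr_validation_error`, ...) naming the
  offending field; an empty dataset after filtering is a warning, not an
  error.
* Hexagon cell ids are axial coordinates under cube rounding; boundary ties
  sit on measure-zero edges and resolve deterministically.

## Limitations

The planar hexagonal backend fixes cell *area*, not the exact icosahedral
cell *shapes*; per-survey flag percentages from a true spherical grid will
differ slightly near cell boundaries. Harmonization is exact-match only by
design, so backbone coverage determines match rates. The swept-area model is
a single survey-level OLS with main effects; surveys with strong
vessel-by-duration interactions should fit their own model and pass the
values in. Flag percentages from real multi-agency surveys depend on the
real data and grid geometry and are not reproduced here.
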