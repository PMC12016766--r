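---
title: "Trait-based climate-change vulnerability assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based climate-change vulnerability assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climvuln)
```

## The assessment

A trait-based vulnerability assessment (TVA) asks, for each species in a
fauna, whether it is (i) *exposed* to a threat — here, climatic change inside
the cells it occupies — (ii) *sensitive*, i.e., poorly equipped to persist in
place, and (iii) short on *adaptive capacity*, i.e., poorly equipped to
adjust or relocate. The three booleans combine into eight discrete
vulnerability categories: species high on all three dimensions are *highly
vulnerable* (category 1); sensitive, low-adaptive-capacity species that are
not exposed are *biologically susceptible* (2); exposed, sensitive species
with high adaptive capacity are *potential adapters* (3); exposed species
with low adaptive capacity but low sensitivity are *potential persisters*
(4); categories 5–7 are the single-dimension cases (*exposed only*,
*sensitive only*, *low adaptive capacity only*); species low on every
dimension are category 8, *low vulnerability*. `assign_category()` encodes
this mapping, `invert_category()` its exact inverse, and both are checked
exhaustively in the test suite.

The motivating application is wildlife-disease surveillance: scanning
surveillance of found-dead wildlife is voluntary and uneven across taxa, so
a species list scored by climate vulnerability can be crossed against the
carcass-submission record to ask whether the species most likely to be
stressed by a changing climate are the ones actually being examined.

## Exposure: climate novelty inside a species' range

Climatic change per grid cell is measured as a standardized Euclidean
distance (SED) between a baseline and a recent multi-year period. Six annual
bioclimatic variables are computed per cell and year from monthly series
(`compute_bioclim()`): annual mean temperature, maximum temperature of the
warmest month, minimum temperature of the coldest month, annual
precipitation, and precipitation of the wettest and driest months. With
$a_k$ and $b_k$ the baseline and recent period means of variable $k$ in a
cell and $s_k$ the baseline interannual standard deviation,

$$\mathrm{SED} = \sum_{k=1}^{6} \frac{(b_k - a_k)^2}{s_k^2}.$$

Standardizing by $s_k$ puts temperatures and precipitation on one scale and
emphasizes shifts that are large relative to historical year-to-year
variability. Two conventions deserve comment:

* **No outer square root.** `compute_sed()` returns the sum of squares
  itself; the square-rooted variant (which makes SED a proper distance) is
  available via `sqrt = TRUE`. Nothing downstream depends on the choice,
  because exposure only uses the tercile *ranks* of SED, and terciles are
  invariant under any monotone transform.
* **Sample SD.** The interannual SD uses the $n-1$ denominator, the standard
  choice for a 30-year climatology. Cells with zero interannual variance are
  an error by default; `sd_floor` offers an explicit epsilon escape for
  degenerate synthetic inputs.

SED values are split into terciles and each cell is classed 0 (lowest), 1,
or 2 (highest). `tercile_breaks()` supports two break definitions:
distribution terciles (the 33.33rd/66.67th percentiles under the
linear-interpolation quantile rule; the default) and `range_thirds`
(equal-width thirds of the value range). Both are offered because the two
readings give visibly different breaks on skewed SED fields; the quantile
default was chosen as the definition consistent with published break values
in this literature. Class boundaries are left-closed at the top: a value
exactly at the upper break is class 2, a value exactly at the lower break is
class 1.

Species exposure is then the class-weighted share of a species' occupied
cells: with $a, b, c$ the *percentages* of occupied cells in classes 0, 1, 2,

$$\mathrm{Exposure}_{\mathrm{raw}} = a \cdot 0 + b \cdot 1 + c \cdot 2 \in [0, 200],$$

rescaled across species to $[0,1]$ by max–min normalization
(`minmax_rescale()`). The percentage (0–100) rather than proportion scale is
fixed purely for reproducibility; it cancels in the rescaling. Two flagging
rules exist because the field uses both: the default `cutoff` rule flags
species with rescaled exposure $\ge 0.5$ (boundary inclusive), and
`top_quartile` flags the species at or above the 75th percentile. The rule
used is recorded in the output. Differences in detectability between species
are deliberately not modelled: occurrence data are presence-only.

## Sensitivity and adaptive capacity: three-point trait scores

Four traits feed each axis, every trait scored 0/1/2 with 2 the most
vulnerable, all traits weighted equally:

| Axis | Trait | Scoring |
|---|---|---|
| Sensitivity | body mass | tercile, low mass → 2 |
| Sensitivity | fossoriality | binary: fossorial → 0, else 2 |
| Sensitivity | strict diurnality | binary: diurnal-only → 2, else 0 |
| Sensitivity | habitat breadth | fixed thresholds: ≥5 types → 0, 2–4 → 1, 1 → 2 |
| Adaptive capacity | dispersal distance | tercile, low → 2; migration-class proxy when absent |
| Adaptive capacity | diet breadth | tercile on item counts, low → 2 |
| Adaptive capacity | reproductive capacity | tercile, low → 2 |
| Adaptive capacity | generation length | tercile, high → 2 |

Reproductive capacity is the lifetime offspring potential
$RC = (L_{\max} - L_{1r}) \times LS \times LPY$ (maximum lifespan minus age
at first reproduction, in years, times litter size times litters per year).
Binary traits never take the middle score: a yes/no trait has no natural
intermediate, and mapping to the extremes preserves equal weighting across
traits. For species lacking a dispersal distance (bats, in the motivating
data set), migratory behavior stands in: sedentary (<10 km) → 2, regional
(10–100 km) → 1, long-distance (>100 km) → 0. A species with neither datum
is an error — no silent imputation.

Continuous traits use the same tercile engine as the climate stage, with the
method independently configurable per stage; both defaults are `quantile`
and are recorded in the run metadata. Axis scores are the sums of their four
traits (0–8), max–min rescaled across species. Species at or above the 75th
percentile of the sensitivity axis are flagged highly sensitive; likewise
for the adaptive-capacity axis (high axis score = low adaptive capacity).
Ties share the flag, so realized flag fractions can deviate from exactly
25% — which is precisely what one observes when many species share an
integer axis sum.

### Break-shift robustness

Because tercile breaks on continuous traits are a modelling choice,
`break_shift_sensitivity()` probes them: one break at a time (first or
second) is moved toward the minimum or the maximum by 1%–33% of the trait's
value range in 1% steps, the trait is re-scored, and the Pearson correlation
between initial and scenario scores (treated as numeric 0/1/2) is reported.
A moved break is clamped at the other break so the class ordering never
inverts; scenarios that collapse all species into one class yield an
undefined correlation, reported as `NA` with a `constant` marker rather than
dropped. At zero shift $r = 1$ exactly, and on evenly spread values $r$
decays monotonically with shift size — both are asserted in the tests
against a from-scratch Pearson computation.

## Surveillance representation

A carcass record enters the audit only if the specimen was completely or
partially necropsied, has finite coordinates, was not collected for a
targeted research project, and falls in the study window. *Complete* means
at least five of the six key organs (brain, heart, lungs, liver, spleen,
kidneys) were examined macroscopically and histologically; *partial* covers
two or more key organs missing or unassessable, macroscopic-only
examination, or absent essential body parts. Each excluded record receives
exactly one reason code, assigned in the fixed order level → coordinates →
targeted → date so exclusion logs are deterministic; an unparseable date is
a `bad_date` exclusion, never a crash. Coordinate validity means present and
finite — a bounding-box check would conflate data errors with legitimate
edge cases, so it is not an exclusion rule.

`representation_summary()` then cross-tabulates included records by
submission year, taxonomic order, and vulnerability category (through the
species→category join), with explicit zero rows for empty categories,
records of unassessed species tallied separately, and unknown species listed
rather than dropped. No single representation-gap statistic is computed: the
mismatch between frequently submitted orders and highly vulnerable orders is
left as a descriptive cross-tabulation, since any scalar summary would
impose an exchangeability assumption across orders that submission data do
not support.

## The packaged reference table

`load_reference_categories()` ships the assignment of 59 terrestrial mammal
species to taxonomic order and vulnerability category that anchors the
package's end-to-end checks. Only the category labels are stored; the
dimension flags are always derived through `invert_category()`, keeping a
single source of truth. The loader verifies a checksum and the table's
invariants (59 species; category counts 2/5/3/2/8/4/4/31; order totals 18
Chiroptera, 16 Rodentia, 10 Carnivora, 8 Eulipotyphla, 5 Cetartiodactyla, 2
Lagomorpha) on every load. `fixture_audit()` pushes the table through the
category machinery and reports the headline counts:

```{r}
audit <- fixture_audit()
audit$headline
audit$by_order
```

## What the synthetic generator emulates — and what it does not

The real inputs of such an assessment (interpolated climate rasters,
atlas-style occurrence grids, a pathology institute's case records) are not
redistributable, so `synthetic_config()` + the `generate_*()` family emulate
their statistical structure:

* **Climate** (`generate_climate()`): ~1 km² cells on a rows × columns grid,
  two disjoint multi-year periods, monthly values built from a sinusoidal
  temperate seasonal cycle (≈3.5 °C in January, ≈17.5 °C in July, 70
  mm/month) plus independent Gaussian noise per variable, precipitation
  floored at 0 mm and `tmin ≤ tmean ≤ tmax` enforced. The recent period is
  shifted by a configurable per-variable trend, optionally weighted by a
  linear gradient toward one grid edge to emulate spatially uneven change.
  Default trend (+1.2 °C mean, +1.5 °C warm extreme, +1.0 °C cold extreme,
  +5 mm/month) matches the magnitude of change observed between the
  1961–1990 and 1991–2020 normals in a northwest-European climate; default
  monthly noise SDs (1.5/2.0/2.5 °C, 30 mm) are of the order of observed
  interannual variability there.
* **Occupancy** (`generate_occurrences()`): presence-only clusters — a disc
  of configurable radius around a cluster center, cells filled independently
  with probability `fill_prob`. Cluster geometry can be pinned per species,
  which the recovery tests use to place species on opposite grid edges.
* **Traits** (`generate_traits()`): log-uniform body mass (4 g–700 kg, the
  span of a European terrestrial mammal fauna), Bernoulli
  fossoriality/diurnality, integer habitat (1–8) and diet (1–12) breadths,
  life-history values with first reproduction clamped below half the maximum
  lifespan so reproductive capacity is always positive. A configurable
  fraction of species is "bat-like": no dispersal distance, migration class
  present.
* **Surveillance** (`generate_surveillance()`): species drawn with
  probability proportional to a per-order submission propensity (default
  weights mimic a scheme where lagomorphs, carnivores and ungulates dominate
  and bats are rare), with configurable fractions of missing coordinates,
  targeted-project flags, macroscopic-only or organ-incomplete examinations,
  and non-necropsy levels, so every inclusion-rule branch is exercised.

Every generator is a pure function of (configuration, seed); the pipeline
run is bit-reproducible from its recorded metadata. What the generator does
*not* emulate: spatial autocorrelation of climate noise between cells,
detection bias in occurrences, trait covariance (real body mass and
generation length are strongly correlated), or seasonality in carcass
submissions. Passing the synthetic-recovery tests therefore demonstrates
that the machinery recovers a known injected signal under the stated noise
model — not that any particular real fauna's scores are correct.

## Numerical choices and degenerate inputs

* Quantiles everywhere use the linear-interpolation definition (R type 7);
  the tests pin this against an explicit $h = (n-1)p + 1$ oracle.
* Tercile breaks require non-identical values; constant axes or traits are
  errors, not silent zeros.
* All flag thresholds are boundary-inclusive (`>=`), and ties share flags.
* An incomplete cell-year (≠ 12 months), a cell missing one of the six
  variables, a nonpositive baseline SD, an occupied cell without a tercile
  class, or a species missing any score or flag all raise errors naming the
  offending entity; the pipeline wrapper prefixes the failing stage.
* Problem sizes: the bundled checks run the full chain on 20 × 20 grids with
  two 30-year periods (400 cells × 720 months), 20 replicate seeds for the
  trend-recovery check, and ≥100 random small instances per oracle
  comparison — sizes at which every stage is exact to double precision
  against brute-force recomputation while the whole suite stays fast.

## Known limitations

The assessment produces *relative* vulnerability within the assessed species
pool: rescaling steps make every score depend on the pool's extremes, so
scores are not comparable across faunas or against differently chosen trait
sets. Trait weights are equal by construction; with only four traits per
axis, each carries substantial weight and alternative scorings can move
species across the quartile thresholds — the break-shift test quantifies
exactly this fragility for the tercile breaks. Exposure inherits every bias
of presence-only occurrence data. None of the surveillance metrics correct
for carcass persistence, detection, or reporting bias; the representation
summary describes the submitted sample, not the living community.
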