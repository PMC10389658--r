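---
title: "Language-environment analysis on constrained Voronoi regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language-environment analysis on constrained Voronoi regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voroling)
```

## The problem

Several strands of research propose that phonological properties of
languages — the balance between consonants and vowels, syllable complexity,
tone, ejectives — co-vary with the climate and terrain where the languages
are spoken. Testing such proposals requires three things that are easy to
get wrong: a defensible *sampling region* around each language's point
location over which environmental variables are summarized; environmental
summaries that are explicit about their statistics, their units and their
temporal windows; and a way to reason about shared ancestry, since related
languages resemble each other for reasons that have nothing to do with
climate. `voroling` implements each step as a tested, seeded, reusable
component, and ships a synthetic-world generator so the whole pipeline can
be validated against planted ground truth.

## Sampling regions: constrained Voronoi cells

Each language is a point (lon/lat, WGS84). Its catchment is built in four
steps:

1. **Equal-area buffer.** A circle of radius 100 km (128 segments) is
   constructed around the point *in the world sinusoidal projection*
   (`x = R·λ·cosφ`, `y = R·φ`, with R the authalic Earth radius), then
   transformed back to lon/lat. Because the projection preserves area, a
   buffer at 70° latitude has the same area as one at the equator (our
   128-gon is within 0.05% of π·r²). In lon/lat space high-latitude buffers
   look stretched east–west; that distortion is cosmetic, not metric.
2. **Coastline clip.** Buffers are intersected with the land multipolygon;
   off-shore area never contributes to a language's environment.
3. **Planar Voronoi partition.** Voronoi cells are computed in *unprojected
   degrees* over a rectangular bounding box. This is a deliberate fidelity
   choice: the GIS lineage of this workflow computes its global Voronoi
   diagram the same way, and we reproduce its geometry including its
   artifacts (below). Coincident points are rejected rather than jittered;
   points within 2° of the antimeridian trigger a warning because the box
   does not wrap.
4. **Constraint.** The sampling region of language *i* is its Voronoi cell
   intersected with the union of *all* land-clipped buffers — not with its
   own buffer.

Step 4 has a consequence worth understanding. If Voronoi adjacency and the
buffers lived in the same metric, the region of language *i* could never
exceed its own buffer: a point nearest *i* that lies inside any equal-radius
buffer is automatically within that radius of *i*. But the degree metric of
step 3 and the kilometre metric of step 1 disagree away from the equator
(one degree of longitude shrinks with cos φ), and coastline clipping makes
the own-buffer denominator smaller still. In rare configurations — a
language whose buffer is heavily clipped, with a neighbour whose wide
degree-footprint buffer reaches across the degree-space bisector — the
region genuinely exceeds the language's own clipped buffer.
`inflation_report()` lists every language's ratio (region area over its own
clipped buffer area) and the flagged fraction. On realistic synthetic
configurations the flagged fraction is a few percent at most and the ratios
are modest, which is the qualitative behaviour this workflow is known for;
the package reports rather than "fixes" it, since the affected regions are
the documented price of the rectangular-box Voronoi construction.

All areas (buffer, clipped buffer, region) are measured by projecting
polygon vertices to the sinusoidal projection and applying the shoelace
formula; hole rings subtract.

## Environmental extraction

**Stations.** Annual station records carry tmin/tmax/tavg (°C) and
precipitation (mm), any of which may be missing. Records are filtered to an
inclusive year window — default 1951–1980, a 30-year span chosen to
precede the late-20th-century warming acceleration while aligning with
climate-normal convention; gridded humidity uses 1960–1980 because that
record starts in 1960. Within a region, the summary is the *grand mean over
all station-year values* together with n, the number of annual values
pooled — not a mean of per-station means, so a long-running station
contributes proportionally to its record length.

**Numeric rasters.** A cell contributes if and only if its centre lies
strictly inside the region (even-odd rule; boundary hits excluded). The
statistic set is: contributing-cell count, null-cell count, minimum,
maximum, range, average, median, first and third quartile, standard
deviation, sample variance (n−1), and coefficient of variation (absent when
the average is zero). Quartiles interpolate linearly between order
statistics (the common "type 7" rule; configurable). These conventions are
stated here because the statistic names alone do not pin them down.

**Categorical rasters.** Land-cover classes are counted per class
(`tall`, `med`, `short`, `water`, `snow`); counts over a region sum to the
region's non-null cell total, and codes missing from the class map are
flagged rather than silently dropped.

**Naming.** Every environmental variable is
`v_<short-name>_<units>__<statistic>` — `v_tavg_dC__avg`,
`v_elev_m__median`, `v_lc_tall_ct__sum`. The double underscore is the
units/statistic separator, so units may not contain underscores while
`lc_tall` and `std_dev` are legal on their own sides.

## Phonological indices

The inventory-derived indices are exact arithmetic on Table-style inputs:

* `OnsCoda = Onset + Coda` (each 0–3, so 0–6);
* `ConsHeavy = OnsCoda + CTotal/4`;
* `CHeavyObstr = OnsCoda + Obstr/3`;
* `CHeavyLog = OnsCoda + ln(CTotal)`;
* `ObsPct = 100·Obstr/CTotal`.

The base of the logarithm in `CHeavyLog` is not fully determined by its
verbal definition; we use the natural logarithm, which is consistent with
the published value range for this index (ln 6 ≈ 1.79 matches the printed
minimum to two decimals, while base-10 or base-2 do not), and we document
it as an assumption rather than a fact.

The **vowel index** is the proportion of vowel symbols among all
classifiable symbols in a short standardized wordlist, ignoring word
boundaries and length marks (the source transcription convention ignores
vowel length). Symbol classification is supplied explicitly per
transcription scheme; the package never guesses an orthography, and symbols
in neither set are reported and excluded.

Tone categories map to an ordinal 0–3 scale: `None` → 0, `Marginal` and
`Simple` → 1, `ModeratelyComplex` → 2, `Complex` → 3. Collapsing marginal
with simple follows the analytical practice of treating "non-tonal or
simple-tone" as the low group while reserving 0 strictly for non-tonal
languages.

On file, derived-index columns are advisory: reading a language CSV
recomputes every derived column from the primitive fields and warns on
discrepancies beyond 1e-6; the recomputed values are authoritative. Hard
invariant violations (more obstruents than consonants, out-of-range
coordinates, flag/count mismatches) are errors that name the offending
rows.

## Relatedness

Genealogical distance is a single 1–10 integer per language pair:
1 = varieties some consider dialects of one language; 2–8 = increasingly
distant relationships within an accepted family; 9 = strongly divided
expert opinion at the highest level; 10 = no accepted relationship (a
language isolate scores 10 against everyone). Distances are stored sparsely
as unordered pairs; an absent pair is read as 10 only when a flagged
isolate is involved, otherwise absence is a validation finding — this
prevents silent misclassification of merely-missing entries. The validator
also reports asymmetric duplicates, range violations and isolate
violations.

Pairwise analysis takes a per-language variable and produces
|x_i − x_j| for every pair with distance 1–9 (unrelated pairs excluded;
dialect pairs filterable), dropping and counting pairs with missing values.
Classes are labelled `Dialect` (1), `Close` (2), `Level 3`…`Level 7`,
`Distant` (8), `Divided Opinions` (9) — the intermediate labels are ours,
since only the endpoints have conventional names. Class summaries are
boxplot statistics: n, median, type-7 quartiles, Tukey whiskers at 1.5 IQR.

## Association statistics

* `linear_assoc()` — ordinary least squares with `r2` equal to the squared
  Pearson correlation and a two-sided t-test on the slope. A constant
  response returns slope 0 and r² 0 by convention (p absent); a constant
  predictor is an error.
* `dichotomize()` — median split (exact-median ties to the lower group) or
  explicit threshold, used to turn continuous environments into
  presence/absence contrasts.
* `chi_square_presence()` — Pearson χ² on the 2×2 table without continuity
  correction by default (the correction is available); expected cell counts
  below 5 are flagged rather than silently tolerated.
* `two_group_means()` — Welch's unequal-variance t-test; the test is named
  explicitly because reported p-values are otherwise ambiguous.
* `group_summary()` — per-ordinal-level boxplot statistics sharing the
  quartile rule above.
* `correlogram()` — pairwise-complete Pearson matrix; zero-variance
  variables are dropped with a warning.

All of these use pairwise-complete deletion and report the n actually
analysed, because environmental coverage differs by variable and honest
per-analysis n is part of the method.

## The synthetic world

`synth_config()` fixes the study conditions; `make_synth_world()` is fully
deterministic given the configuration (per-stage sub-seeds derive from the
root seed, so stages can be regenerated independently, and a fixed
configuration yields byte-identical serialized output).

* **Land** is a union of irregular star-shaped blobs grown until the land
  fraction of the 80°×60° extent reaches its target (default 0.35,
  tolerance ±0.04; the last blob is rescaled to land on target).
* **Language points** fall on land with latitudinal density
  ∝ exp(−bias·|lat|/90) (default bias 2 — denser near the equator, as real
  language density is) and a 0.1° minimum separation.
* **Rasters** (0.5° cells): elevation is a smooth Gaussian random field
  (white noise convolved with a Gaussian kernel of 3° correlation length;
  sea level 0); temperature is 27 °C at the sea-level equator minus
  0.6 °C per degree of |latitude| (an equator-to-pole-style gradient) minus
  6.5 °C per km of elevation (the standard-atmosphere lapse rate) plus
  smooth noise (1.5 °C); humidity, biomass and precipitation are increasing
  transforms of temperature with their own smooth noise — hence positively
  inter-correlated with each other and negatively with elevation, the
  correlation structure real climate data exhibit; land cover derives from
  biomass terciles with water and snow masks.
* **Stations** (50 per million km² of land) have per-latitude intensity
  ∝ max(0, 1 + north_bias·lat/90), emulating the historical northern
  coverage bias of instrumental networks; each station yields one record
  per year (1951–1980) equal to the local raster value plus 0.5 °C
  observation noise, with 2% missingness per parameter.
* **Phoneme inventories** encode the planted effect: latent heaviness
  `h_i = a + b·T_i + ε_i` with defaults a = 8, b = −0.15 index units per
  °C, ε ~ N(0, 1). `h_i` is decomposed into integer `OnsCoda` ∈ 0–6 and
  `CTotal` ≥ 6 with `OnsCoda + CTotal/4` within 0.125 of `h_i`; every
  feasible `OnsCoda` gives the same rounding error (the `CTotal` step is
  0.25), so the tie-break picks the decomposition whose `CTotal` is nearest
  22, a typical consonant-inventory size — giving realistic joint variation
  in both components. Latent values outside the feasible range are clamped
  with a warning. All other parameters come from marginal distributions,
  independent of the environment unless the optional altitude→ejectives or
  humidity→tone links are switched on (both default off, so trait analyses
  have a clean null).
* **Genealogy**: languages are partitioned into families (mean size 6);
  each family gets a random binary branching structure; within-family
  distance is 2 plus the branching levels separating the pair (capped at
  8), 1% of cross-family pairs between multi-member families are marked 9,
  the rest 10; singleton families are isolates.

What the generator does *not* emulate: real-Earth geography, real language
families and their areal structure, phoneme co-occurrence constraints
beyond marginals, spatial autocorrelation of language traits, and the
displacement histories of speaker populations. Tests passing on this world
therefore show that the pipeline's computations are correct and that the
planted effect is recovered without bias — they do not show that any
particular real-world association is causal or correctly sized.

## Validation design and problem sizes

The test suite validates each operation against independent oracles:
point-in-polygon against a hand-written ray-casting loop, zonal statistics
against a brute-force per-cell loop with explicit moment formulas and
direct order-statistic interpolation, Voronoi membership against
nearest-seed classification on dense grids, linear fits against the
closed-form normal equations, Welch p-values against the textbook formula,
and χ² against the closed-form statistic. The headline validation runs
are: constrained-region membership on a 1000×1000 grid over 25 languages
(≥ 99.5% agreement required; areas must partition the buffer union within
0.5%); zonal statistics on 100 random region/raster pairs (exact counts,
1e-9 moments); slope recovery over 200 replicates at n = 300 (mean within
3 standard errors of −0.15; ≤ 10% of null replicates significant); a
1000-replicate χ² null at n = 500 (type-I error within [0.035, 0.065] at
α = 0.05); and 100 end-to-end pipeline replicates at n = 60 languages
(≥ 95% significant recovery of the planted sign, ≤ 10% under the null).
These sizes were chosen so the full suite validates every guarantee at
desk scale; `scripts/acceptance.R` recomputes the same quantities from
scratch for any seed.

## Numerical choices and degenerate inputs

* Buffer circles use 128 segments; the stated tolerances assume this.
* Cell inclusion is strict-interior with the even-odd rule, so a cell
  centre exactly on a region boundary counts for no region (and boundary
  cases are measure-zero for continuous data).
* Quartiles are type 7 everywhere (extraction, class summaries, boxplot
  statistics) and configurable in one place.
* Variance is the n−1 sample variance; the coefficient of variation is
  absent when the mean is zero.
* Coincident language points are an error, not a jitter; empty clipped
  buffers (a point off all land) are kept as empty regions and flagged.
* The relatedness generator caps within-family distances at 8; deeper trees
  do not overflow the scale.
* Zero-variance variables: rejected as regression predictors, conventional
  (slope 0, r² 0) as responses, dropped from correlograms, and an error for
  median splits.

## Limitations

The Voronoi partition is planar in degrees by design, inheriting the
documented distortion of that choice; no geodesic Voronoi is offered. The
pipeline performs no mixed-model or phylogenetic control for relatedness —
the distance tables are descriptive. Adapters for real raster and station
archives exist only insofar as the standard formats (CSV, ESRI ASCII grid,
GeoJSON) are supported; acquiring and harmonizing real global datasets is
out of scope. Statistical analyses are non-spatial: no correction for
spatial autocorrelation of either languages or environments is applied.
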