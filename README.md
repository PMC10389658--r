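# voroling

Tools for studying whether the sound structure of languages is associated
with the environments in which they are spoken — temperature, humidity,
precipitation, vegetation density and altitude.

Research in ecolinguistics and phonological typology repeatedly runs into
the same methodological problems: a language's "location" is a single point,
but climate must be summarized over an area; nearby languages compete for
the same terrain; and similarities between languages can reflect shared
ancestry rather than shared environment. `voroling` implements a complete,
tested pipeline for this class of analysis:

* **Constrained Voronoi sampling regions.** Every language gets a 100 km
  buffer built in the world sinusoidal equal-area projection (so its area is
  latitude-independent), clipped to the coastline, and partitioned among
  neighbours by a planar Voronoi diagram. The sampling region of language
  *i* is its Voronoi cell intersected with the *combined* land-clipped
  buffers — reproducing, deliberately, the region-inflation artifact of the
  GIS workflow this mirrors (a small fraction of regions can exceed their
  own buffer area; `inflation_report()` quantifies it).
* **Environmental zonal summaries.** Annual weather-station records
  (default window 1951–1980) are pooled into grand means per region; numeric
  rasters (elevation, specific humidity, biomass) are summarized by count,
  null-cell count, min/max/range, mean, median, quartiles, standard
  deviation, variance and coefficient of variation; categorical land-cover
  rasters by per-class cell counts. Output columns follow the
  `v_<name>_<units>__<stat>` grammar (e.g. `v_tavg_dC__avg`,
  `v_elev_m__median`, `v_lc_tall_ct__sum`).
* **Phonological typology indices.** The consonant-heaviness family
  (`ConsHeavy = OnsCoda + CTotal/4`, `CHeavyObstr = OnsCoda + Obstr/3`,
  `CHeavyLog = OnsCoda + ln CTotal`), the obstruent percentage, and the
  wordlist vowel index (vowel symbols over all classifiable symbols).
* **Genealogical distance tables.** The 1–10 relatedness scale
  (1 = potential dialects, …, 9 = divided expert opinion, 10 = no accepted
  relationship), with validation, pairwise trait/environment difference
  tables excluding unrelated pairs, and per-class boxplot summaries.
* **Association statistics.** Linear fits with R² and a slope test,
  χ² presence/absence tests of traits against dichotomized environments,
  ordinal group summaries (e.g. humidity by tone-system complexity), Welch
  two-group mean comparisons (e.g. altitude with/without aspirates), and
  Pearson correlograms.
* **A synthetic world generator.** Seeded land/sea geometry, language
  points densest near the equator, spatially autocorrelated climate rasters
  with realistic inter-correlations, a station network with configurable
  hemispheric coverage bias, phoneme inventories with a *planted* linear
  effect of temperature on consonant heaviness
  (`h = a + b·T + ε`), and a random genealogy — so every pipeline stage can
  be validated against known truth without downloading anything.

## Worked example

```r
library(voroling)

# a reproducible miniature world: 60 languages, ~1/3 land, planted
# temperature effect on consonant heaviness (b = -0.15 per degree C)
world <- make_synth_world(synth_config(seed = 1))

# constrained Voronoi sampling regions (100 km equal-area buffers)
regions <- build_sampling_regions(world$languages, world$land,
                                  bounding_box = world$config$extent)
summary(regions$region_area)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   12844   24652   29969   27539   31403   31403

# environmental summaries within each region, then the master table
env <- extract_environment(regions, world$stations, world$rasters)
master <- assemble_master_table(world$language_table, regions, env)
dim(master)
#> [1] 60 88

# the replication regression: consonant heaviness vs mean annual temperature
linear_assoc(master$v_tavg_dC__avg, master$ConsHeavy)
#> linear fit: n = 40, slope = -0.123069, intercept = 7.34061, R2 = 0.2061, p = 0.003252

# pairwise differences by genealogical distance class
vals <- setNames(master$ConsHeavy, master$id)
head(summarize_by_class(pairwise_differences(vals, world$relatedness)), 3)
#> # A tibble: 3 x 8
#>       d class_label     n median    q1    q3 whisker_lo whisker_hi
#>   <int> <chr>       <int>  <dbl> <dbl> <dbl>      <dbl>      <dbl>
#> 1     2 Close          64   1.12 0.5    2.5           0       3.75
#> 2     3 Level 3        37   1.25 0.5    2             0       3.5
#> 3     4 Level 4        71   1.5  0.625  2.25          0       4.25
```

The fitted slope is negative and significant, as planted. An isolated
buffer has area π·100² ≈ 31,416 km², which is why free-standing languages
dominate the upper quartile of region areas; smaller regions belong to
coastal or crowded languages. Only 40 of the 60 languages have
station-derived temperature — the regression reports the n actually
analysed, mirroring how missing environmental coverage is handled
throughout.

A command-line wrapper is installed with the package
(`inst/cli/voroling`): subcommands `synth`, `regions`, `extract`,
`pairwise`, `analyze` and `run` tie the stages into seeded, manifest-logged
runs (`voroling run --seed 7 --out out/`).

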