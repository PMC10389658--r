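Package: voroling
Title: Constrained-Voronoi Sampling Regions and Environmental Correlates of
    Phonological Typology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-language environmental sampling regions as constrained
    Voronoi cells (100 km equal-area buffers clipped to coastlines and
    partitioned by a planar Voronoi diagram), summarizes weather-station and
    raster environmental data within each region, computes phoneme-inventory
    typological indices such as consonant heaviness and the wordlist vowel
    index, analyses pairwise genealogical distances on a 1-10 relatedness
    scale, and provides the replication statistics (linear associations,
    chi-squared presence/absence tests, group summaries, correlograms) used in
    language-environment association studies.  A seeded synthetic-world
    generator with planted environmental effects supplies test inputs for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    ggplot2,
    jsonlite,
    polyclip,
    rlang,
    sp,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
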