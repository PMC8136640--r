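Package: choroscan
Title: Chorotype Detection by Spatial Congruence Analysis of Species Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies chorotypes (groups of species with congruent
    geographic ranges) from vector range maps by Spatial Congruence
    Analysis: pairwise range overlaps are scored with a symmetric
    congruence index, assembled into a species-level congruence network,
    and the network is swept over an explicit grid of congruence
    thresholds.  At each threshold a breadth-first expansion from a
    reference species collects directly and indirectly congruent ranges
    until the group closes, yielding partial chorotypes with depth, area
    and cohesion metrics.  Includes cross-reference post-processing
    (synonymous, nested and independently overlapping chorotypes),
    deterministic synthetic range generators for method evaluation, plain
    text readers and writers for WKT and GeoJSON range maps, and ggplot2
    visualisations of ranges and congruence diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    polyclip,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
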