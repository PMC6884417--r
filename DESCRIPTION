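Package: blastoquant
Title: Quantifying Transcript Patterning and Lineage Imbalance in Twin Mouse Blastomeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of monozygotic twin mouse
    embryos produced by bisection of 2-cell embryos. Implements an
    image-derived eccentricity statistic for mRNA FISH signal distribution
    (distance between an ROI's geometric centroid and its intensity-weighted
    centre of mass on equatorial maximum-intensity projections), twin-pair
    lineage-count ratio statistics (per-germ-layer C-high/C-low ratios,
    epiblast sufficiency classification, singleton/complete-pair accounting
    and the Fisher allocation test), hierarchical-clustering twin-pair
    recovery, and seeded synthetic generators for confocal z-stacks, lineage
    count tables and blastomere-pair expression matrices that emulate the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
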