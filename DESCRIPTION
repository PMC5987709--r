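Package: perihalo
Title: Quantitation of Perilymphatic Exosome Halos and Dendritic-Cell
    Migration Assays
Version: 0.1.0
Authors@R:
    person("Perihalo", "Maintainers", email = "maintainers@perihalo.dev",
           role = c("aut", "cre"))
Description: Analysis toolkit for studies of endothelial exosome fractions
    and leukocyte migration: per-track chemotaxis and chemokinesis
    statistics (chemotactic index and displacement, speed, migratory angle
    change), cell-shape circularity from contour polygons, perivascular
    fluorescence-halo band widths and diameter ratios from cross-sectional
    line profiles, six-plex isobaric-tag (TMT) reporter quantitation with
    Top3 protein abundances, ratio/significance analysis and protein-cluster
    enrichment, point-to-vessel distance statistics with a complete-spatial-
    randomness normalization, transwell calibration, particle-size histogram
    averaging and membrane pore geometry. Every input class has a seeded
    synthetic generator with known ground truth, so the full pipeline is
    exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
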