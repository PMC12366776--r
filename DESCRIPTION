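Package: dropletmorph
Title: Morphometry of Organoids Confined in Collagen Droplets
Version: 0.1.0
Authors@R: person("Droplet", "Morph Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of organoid growth inside nanolitre collagen
    droplets from 2-D binary segmentation masks. Provides per-region shape
    descriptors (area, perimeter, moment-ellipse axes, compactness, shape
    irregularity index), skeleton-based branch detection with the
    spheroid/branched classification used in droplet organoid screening,
    droplet contraction and organoid-boundary proximity dynamics, population
    homogeneity statistics (polydispersity index, branched fraction), a
    Poisson encapsulation and throughput model for droplet microfluidics, and
    a ground-truthed synthetic mask generator so the whole pipeline is
    testable without microscopy data. Includes a minimal 16-bit label TIFF
    reader/writer and a config-driven command line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
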