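Package: laminscape
Title: Mesoscale Genome Folding, Radial Nuclear Organization and Chromatin
    Dynamics Analytics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative toolkit for studying how nuclear lamina perturbation
    reshapes genome organization across scales. Implements LAD-aware Hi-C
    contact-probability scaling analysis (segment-classified P(s) curves and
    power-law exponent fits, interchromosomal change matrices, compartment
    eigenvectors, TAD/LAD overlap summaries), radial nuclear geometry
    (concentric ring partitions with 2k-1 area normalization, fixed-width
    peripheral ribbons, morphological periphery/interior masks), spatial
    signal statistics (ring occupancy, normalized regional intensity for
    localization microscopy, coefficient of variation, average-shifted
    histogram reconstruction, foci distance statistics), spectroscopic
    chromatin dynamics (spectral-variance Sigma maps, temporal variance,
    fractional moving mass, autocorrelation-decay diffusion, ribbon-regional
    aggregation), gene-expression post-processing (DEG filtering, gene-vs-LAD
    classification, Gini transcriptional divergence), and seeded synthetic
    generators that emulate every input so the full pipeline is testable
    without raw microscopy or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: HiC, Epigenetics, GeneRegulation, Software, CellBiology,
    Spatial, SingleCell
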