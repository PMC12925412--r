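Package: wingscape
Title: Quantitative Wing Colour-Pattern and DNA-Barcode Analysis for Moth Taxonomy
Version: 0.1.0
Authors@R:
    person("Mikael", "Korhola", email = "mikael.korhola@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for integrative taxonomy of moths from
    museum specimens. Converts calibrated cone-catch wing images to
    receptor-noise-limited (RNL) chromaticity channels, measures pattern
    granularity with a Gabor filter bank across spatial scales and
    orientations, summarises specimens with principal component analysis and
    linear mixed models of wing metrics on sex, taxon, wear, specimen age and
    geography, and analyses mtCOI barcode alignments with Kimura 2-parameter
    distances, haplotype collapsing and median-joining networks. Includes a
    synthetic wing-image and barcode generator with settable effect sizes so
    the whole pipeline is testable without access to the physical specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
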