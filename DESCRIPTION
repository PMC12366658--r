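Package: chimeraDecomp
Title: Decomposition of Cellular Trait Divergence from Reciprocal
    Interspecies Chimeras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much of the evolutionary divergence in a
    cellular trait (gene expression, cell-state ratios, protein levels) is
    cell-intrinsic, cell-extrinsic, or due to an intrinsic-extrinsic
    interaction, using the four species-environment combinations measured
    in reciprocal interspecies chimeras (host mouse, host rat, donor
    mouse, donor rat). Includes species assignment from dual-genome
    alignments, quality-control and gene filters, pseudobulking,
    equal-depth resampled count normalization, a preranked gene-set
    enrichment engine with a symmetric rank transform for unsigned
    metrics, trait-level and covariate analyses, immunofluorescence image
    quantification, and a synthetic reciprocal-chimera data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
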