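Package: chromoscape
Title: Single-Cell Chromatin Activity Landscapes from Lineage-Resolved
    Reporter Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lineage-resolved chromatin activity landscapes from
    per-nucleus fluorescent reporter intensity time series in Caenorhabditis
    elegans embryos. Provides Sulston-nomenclature lineage algebra (lowest
    common ancestors, lineage distances, fate profiles and divergence, clonal
    tissue lineages, left-right symmetric pairs), depth-dependent fluorescence
    attenuation correction, instantaneous expression quantification with a
    null-calibrated cutoff, replicate integration into consensus cells-by-
    positions landscapes, divergence statistics (lineage-distance
    stratification, transition-point detection, lineage-normalized cell
    clustering, tissue and left-right analyses), genomic co-dynamics clustering
    with hypergeometric enrichment, and a fully seeded synthetic embryo
    generator with ground-truth sidecars so every stage is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
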