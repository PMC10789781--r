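Package: radialmeth
Title: Radiation-Induced DNA Methylation in the Context of Radial Nuclear
    Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ionizing-radiation epigenomics: per-probe
    differential methylation calling on M values with effect-size and
    versus-control filters, distance-based grouping of differentially
    methylated probes (DMPs) into regions (DMRs) with a probe-label
    permutation null, equal-occupancy radial nuclear layering from a Hi-C
    score track, histone-mark and regulatory-region enrichment statistics,
    and gene-expression persistence validation. Ships a synthetic-data
    generator that emulates every input kind (bimodal Beta methylation with
    replicate structure, particle-specific persistent or decaying planted
    effects, layer-dependent effect magnitude, peripherally enriched
    heterochromatin peaks, negative-binomial count trajectories) with planted
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
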