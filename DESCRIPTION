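Package: chondroclass
Title: Multi-Omics Consensus Subtyping of Chondrosarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular subtyping of chondrosarcoma from bulk mRNA, microRNA and
    DNA methylation profiles. Implements independent component analysis (JADE)
    for data-driven removal of non-neoplastic and technical signal,
    feature-resampled hierarchical consensus clustering with cophenetic
    selection of the cluster number, integration of per-omics co-classification
    matrices into a multi-omics similarity clustered by resampled partition
    around medoids with dispersion-based selection of the cluster number, and
    an mRNA-only surrogate classifier (moderated-t marker selection, linear
    support vector machines, repeated cross-validation) that reproduces the
    single-omics and multi-omics subtype calls from gene expression alone.
    Ships a synthetic multi-omics cohort generator with planted subtype
    structure, contamination and technical confounds so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    limma,
    cluster
Config/testthat/edition: 3
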