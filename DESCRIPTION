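Package: phytodistricts
Title: Quantitative Biogeographic Regionalization from Species Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for delimiting phytogeographic districts
    from species occurrence records. Occurrences are curated and assigned to a
    regular geographic grid, poorly sampled cells are merged into neighbours,
    and pairwise species turnover between cells is measured with the
    beta-Simpson dissimilarity index. Districts are delimited by WPGMA
    hierarchical clustering with reassignment of minor groups and validated by
    a multi-response permutation procedure (MRPP). Compositional gradients are
    summarised by non-metric multidimensional scaling, and environmental
    drivers of composition are identified by redundancy analysis with
    permutation-based forward selection and by post-hoc vector fitting onto the
    ordination. Exclusive-species pools per district are summarised as
    minimum-spanning-tree biogeographic tracks. A synthetic-landscape generator
    with planted districts, exclusive and shared species pools, heterogeneous
    sampling effort and district-structured environmental layers makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    geosphere,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
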