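Package: ovascreen
Title: Germline-Specific Gene Screening from Replicate-Free RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies previtellogenic female germline-specific genes from an
    eleven-sample, single-replicate RNA-seq count matrix spanning mosquito
    developmental stages, sexes and ovary dissections. Implements a
    replicate-free negative-binomial conditional exact test with a fixed
    biological coefficient of variation, Benjamini-Hochberg FDR control, a
    four-contrast ovary-versus-soma intersection, RPKM normalization, a
    pseudocount fold-ratio filter, and embryo-deposition refinements
    (follicle-cell and zygotic-expression flags, blood-meal response classes).
    Also provides droplet digital PCR Poisson quantification and delta-delta-Ct
    relative quantification for measuring transcript knockdown, three-taxon
    Venn partitioning of ortholog-group membership, and a synthetic count
    generator with planted gene classes for end-to-end validation.
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
    tidyr,
    tools,
    utils,
    withr
Suggests:
    BiocGenerics,
    edgeR,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
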