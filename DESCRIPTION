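Package: lethalscan
Title: Detection of Recessive Lethal Haplotypes and Deletions from Pedigreed
    Livestock Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-stage inference pipeline for mapping recessive lethal
    chromosomal deletions in pedigreed livestock populations. Implements
    weighted mixed-model association scans on de-regressed proofs (sire and
    animal models), random-haplotype models with likelihood-ratio tests, a
    sliding-window missing-homozygote Poisson test, deletion-carrier calling
    from Hardy-Weinberg deviation, SNP-array Log2R intensity loss and
    sequencing read-depth halving, and a sire-by-maternal-grandsire
    mating-type stillbirth analysis. A pedigree gene-drop simulator with a
    planted recessive lethal deletion provides fully known ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
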