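Package: ovistep
Title: Single-Step Genomic Evaluation with Major-Gene Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genetic evaluation toolkit for dairy-sheep style breeding
    programmes built around Henderson's mixed-model equations. Implements
    pedigree BLUP, single-step genomic BLUP (ssGBLUP) with the combined
    pedigree-genomic H matrix, four weighted ssGBLUP strategies that
    re-weight SNPs by the variance they explain (classical and windowed
    mean/maximum/sum variants), the multiple-trait Gene Content model that
    carries the allele count at a known causal locus as a correlated trait,
    and Gibbs samplers for the (co)variance components. A gene-dropping
    population simulator with LD-structured founder haplotypes and a
    pleiotropic major locus makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
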