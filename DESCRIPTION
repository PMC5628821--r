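Package: snpwave
Title: Multi-Breed SNP Genotyping Array Design and Validation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design and validate medium-density SNP genotyping
    arrays for livestock populations with several breeds, modelled on the
    water-buffalo (Bubalus bubalis) 90K Axiom design. Covers multi-breed
    variant intake from VCF (discovery filters, per-breed minor allele
    frequencies, species-corrected reference, 71-mer flank extraction),
    probe flank evaluation with a documented deterministic conversion-score
    surrogate, wave-based greedy gap-minimizing panel selection driven by a
    breed-weighted gap-filling score, post-genotyping probeset quality
    classification (PolyHighResolution and related Axiom categories), and a
    two-step GRAMMAR genome-wide association scan with genomic control.
    Includes a synthetic-data generator (Balding-Nichols breed divergence,
    genotypes, pedigrees, phenotypes with known heritability) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
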