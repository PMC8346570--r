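Package: bilinevo
Title: Multi-Lesion Evolution Analysis of Gallbladder Carcinoma and
    Coexisting Biliary Intraepithelial Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of gallbladder
    carcinoma (GBC) from multi-region whole-exome data of co-resected
    lesions (GBC, low-grade and high-grade biliary intraepithelial
    neoplasia, and matched normal tissue). Implements somatic-call
    filtering with a cross-sample rescue rule, tumor mutation burden,
    96-context mutational-signature decomposition by non-negative least
    squares, exhaustive maximum-parsimony lesion phylogenies with
    bootstrap support, classification of BilIN-dependent versus
    BilIN-independent evolutionary paths with copy-number and
    loss-of-heterozygosity (LOH) corroboration, ancestral LOH interval
    analysis, cancer-cell-fraction based clone clustering with a
    binomial-mixture model, Jaccard-similarity seeding classification,
    and cohort-level group statistics. A seeded synthetic multi-region
    tumor generator with ground truth makes the whole pipeline testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    pracma,
    jsonlite,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
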