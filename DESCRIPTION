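Package: mdrscan
Title: Exhaustive Pairwise Variant Interaction Scanning with Multifactor
    Dimensionality Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects pairs of genomic variants jointly associated with a
    binary (case/control) phenotype. An exhaustive pairwise chi-square
    association scan over 3x3 genotype-combination tables reduces the pair
    space, after which Multifactor Dimensionality Reduction (MDR) builds
    cross-validated high-risk/low-risk contingency-table classifiers for
    each surviving pair and selects the pairs that rank in the top fraction
    of held-out prediction power in every cross-validation fold. Includes
    a one-hot genotype CSV reader/writer, a Hardy-Weinberg case-control
    simulator with plantable penetrance-table epistasis, multiple-testing
    arithmetic, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
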