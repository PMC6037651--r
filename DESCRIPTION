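Package: cytophylo
Title: Karyotype-Character Parsimony Phylogenetics and Flow-Cytometric
    Genome-Size Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative cytogenetics at desk scale: validation and
    summary of karyotype descriptions (diploid number, chromosome morphology
    classes, sex-chromosome systems, B chromosomes, banding and NOR patterns),
    encoding of karyotype features into discrete character matrices, exact
    maximum-parsimony inference (Fitch and Sankoff small parsimony, exhaustive
    enumeration and branch-and-bound search), nonparametric bootstrap split
    support with strict-consensus scoring, and genome-size estimation from
    propidium-iodide flow cytometry with an internal standard. Includes
    seeded synthetic-data generators (character evolution on a known tree,
    two-population fluorescence runs, random valid karyotypes) so that every
    stage can be tested against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
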