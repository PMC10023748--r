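Package: prestor
Title: Multi-Condition Correction of Enzyme Turnover Numbers in
    Protein-Constrained Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Corrects enzyme turnover numbers (kcat) in protein-constrained
    genome-scale metabolic models by jointly fitting measured growth rates
    and enzyme abundances across multiple experimental conditions with a
    single linear program (the PRESTO approach). Includes GECKO-style model
    augmentation from gene-protein-reaction rules, condition-specific
    constraint scenarios, cross-validated selection of the regularisation
    weight, post-optimal variability analysis and sampling of alternative
    corrections, the GECKO control-coefficient correction heuristic as a
    baseline, growth-prediction validation, hypergeometric pathway
    enrichment, and a synthetic-data generator with known ground-truth
    kcat deflations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
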