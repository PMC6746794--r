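Package: lgsmr
Title: Unweighted Lipid Genetic Scores for Mendelian Randomization in
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for Mendelian-randomization analyses of blood lipid
    traits and colorectal cancer risk using unweighted allele-count
    genetic scores. Implements GWAS-catalog-style instrument selection
    (genome-wide significance, population restriction, LD pruning at
    r^2 > 0.2 within chromosomal regions, pleiotropy and excluded-trait
    filters), risk-allele alignment and score construction, covariate-
    adjusted case-control logistic association including odds ratios per
    10 risk alleles, Hardy-Weinberg quality control, genotype principal
    components, statin-use instrument validation, analytic power for
    binary-outcome allele-score MR, and a synthetic cohort generator
    with linkage-disequilibrium blocks and confounding-by-indication
    structure for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
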