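Package: pedpop
Title: Pedigree-Based Population Size Estimation from Noninvasive SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates wildlife population size from pedigrees reconstructed
    out of noninvasively collected SNP genotypes. Implements the
    Creel-Rosenblatt estimator with full-sibling screening, dam:sire ratio
    inference of missing parents and sex-specific mortality correction;
    rarefaction (accumulation-curve) estimation with the Kohn saturation
    model; Lynch-Ritland pairwise relatedness for pedigree verification;
    likelihood-based parentage assignment with a genotyping-error model;
    sample QC, SNP-based species and sex assignment, genotype matching and
    consensus calling; and an individual-based demographic simulator of a
    polygynandrous, female-philopatric population that generates fecal-sample
    genotype data with allelic dropout and typing error for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
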