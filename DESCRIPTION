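Package: sowtherm
Title: Genetic Parameters for Thermotolerance Indicators in Lactating Sows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and genomic analysis of heat-stress indicator traits in
    lactating sows. Generates SNP genotypes, in-barn climate series and
    phenotypes with a known variance structure; derives vaginal-temperature
    subsets, respiration rate and respiration efficiency with the standard
    filtering rules; performs genotype quality control and builds a VanRaden
    (method 1) genomic relationship matrix; estimates variance components of
    repeatability and animal models with a Gibbs sampler; selects in-barn
    climate covariates by the deviance information criterion; and reports
    heritabilities, repeatabilities, genetic correlations, genomic estimated
    breeding values and their theoretical accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    coda,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
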