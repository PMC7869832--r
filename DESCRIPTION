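Package: admixprs
Title: Simulating Polygenic Risk Score Transferability Across Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded, configurable simulation study of polygenic risk score
    (PRS) transferability between European-like, African-like, and admixed
    populations. Simulates genotypes under a two-population out-of-Africa
    demographic model (via a bundled msprime bridge), generates admixed
    individuals with true local-ancestry tracts, draws liability-threshold
    case-control phenotypes with known genetic truth, runs allele-count
    GWASs with fixed-effects meta-analysis, builds PRSs by LD clumping and
    p-value thresholding under several variant-selection and weighting
    strategies (including local-ancestry weighting and a two-PRS linear
    mixture), and evaluates prediction accuracy as a function of global
    genetic ancestry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
SystemRequirements: python3 with msprime (>= 1.0) and tskit, used for
    coalescent genotype simulation via inst/python/coalescent_sim.py
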