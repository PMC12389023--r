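Package: gmsir
Title: Genotype-Stratified Analysis of Alcohol, Gut Microbiota, and Insulin Resistance
Version: 0.1.0
Authors@R: person("GMS", "Maintainers", email = "maintainers@gmsir.org", role = c("aut", "cre"))
Description: Tools for genotype-stratified analyses linking alcohol consumption,
    gut microbial species, and insulin resistance. Implements HOMA-based
    metabolic phenotyping with diabetes exclusion, prevalence/abundance
    filtering and centered log-ratio transformation of species count tables,
    bias-corrected per-species differential abundance against ordinal alcohol
    level within ADH1B rs1229984 genotype strata, a correlation-whitened
    weighted gut microbiome score (GMS), tertile-stratified logistic and
    rank-based robust regression with product-term interaction tests, a
    seeded synthetic-cohort generator with planted effects for parameter
    recovery testing, and an end-to-end pipeline driven by a single config.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
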