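Package: sesBrainMap
Title: Multi-Output Ridge Mapping of Socioeconomic Status onto Brain Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population-scale analysis of how socioeconomic status (SES) is
    reflected in atlas-level brain structure. Six SES indicators are mapped
    jointly onto region gray-matter volumes and white-matter tract
    microstructure with multi-output ridge regression, bootstrap-bagged
    coefficient estimates, and permutation max-statistic family-wise-error
    inference. Dedicated laterality statistics (hemisphere-by-sign
    contingency tests, homologue correlations) quantify hemispheric
    asymmetry of the brain-SES pattern. A seeded synthetic-cohort generator
    with planted lateralized effects supports end-to-end validation, and a
    meta-analytic annotation module profiles coefficient maps against
    region-by-term association matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    caret,
    yaml,
    optparse,
    testthat (>= 3.0.0)
biocViews: StatisticalMethod, Regression, Epidemiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
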