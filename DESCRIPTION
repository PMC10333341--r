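Package: ecnet
Title: Eigenvector-Centrality Analysis of Parcellated Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R: person("Alex", "Morgan", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Carries a parcellated resting-state fMRI cohort from raw
    region-of-interest time series to group-level inference. Provides AR(1)
    pre-whitening with motion, white-matter and CSF confound regression,
    per-subject eigenvector centrality over the shifted correlation network,
    max-statistic permutation tests with Freedman-Lane covariate adjustment
    for hubs of differential connectivity, exposure-by-diagnosis moderation
    models with simple slopes, weighted quantile sum regression of a
    multi-scale symptom mixture on hub centrality, and a synthetic cohort
    generator with planted effects so the whole pipeline is testable end to
    end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
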