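Package: namerel
Title: Reliability of Picture-Naming Response Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reliability of participants' mean response
    speed in picture-naming experiments. Provides trial-level data validation,
    response classification and exclusion reporting; a synthetic-data generator
    with crossed participant and item random effects and known ground truth;
    Bayesian hierarchical estimation (via JAGS) of split-half and test-retest
    reliability as the correlation of by-participant random effects; graded
    interpretation of reliability correlations with region-of-practical-
    equivalence bands; Bayesian estimation of a Pearson correlation under a
    shifted and scaled Beta prior; stimulus-list balancing by randomized
    cosine-similarity matching; and reliability-attenuated power planning for
    correlational individual-differences designs using the exact sampling
    distribution of the correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
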