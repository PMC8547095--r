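Package: sigrevert
Title: Disease-Signature Derivation and Drug-Induced Signature Reversion for
    Multi-Omic Mouse Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for deriving Alzheimer's-disease expression
    signatures from genotype-by-age interaction models and scoring their
    reversion by drug treatments. Provides empirical-Bayes moderated
    differential expression with batch covariates, iTRAQ-style proteomics
    normalization and per-protein mixed models, mRNA-protein decoupling
    analysis, connectivity-map-style signature-reversion scoring against a
    randomized-signature null, a multi-query virtual compound-screening
    scheme over bioactivity signature spaces, and cognitive-test summary
    statistics. A negative-binomial multi-omic study simulator with ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    lme4,
    multcomp,
    ranger,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
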