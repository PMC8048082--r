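Package: mtqsarx
Title: Multitarget QSAR Classification with Box-Jenkins Deviation Descriptors
Version: 0.1.0
Authors@R:
    person("mtqsarx", "developers", email = "mtqsarx@example.org", role = c("aut", "cre"))
Description: Builds and validates multitarget (mt-)QSAR classification models
    for datasets whose rows combine a compound with an experimental condition
    tuple (biological target, cell line, assay, ...). Input molecular
    descriptors are converted into condition-dependent deviation descriptors
    by four Box-Jenkins moving-average operators fitted strictly on training
    data, so that the validation set never leaks into descriptor statistics.
    Provides three leakage-safe dataset division schemes (pre-defined tags,
    random, k-means cluster analysis), stepwise and sequential-forward
    linear discriminant analysis with Wilks' lambda diagnostics, six
    non-linear classifiers with exhaustive grid-search hyperparameter
    tuning, Y-randomisation extended to condition columns, applicability
    domain estimation (standardisation rule for linear models, prediction
    confidence for non-linear ones), condition-wise prediction reports and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    FNN,
    quadprog,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
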