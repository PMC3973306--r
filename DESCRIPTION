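Package: methcal
Title: Cross-Tissue Calibration and Prediction of DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-CpG statistical calibration of DNA methylation measured in an
    easy-to-access surrogate tissue (for example peripheral blood leukocytes)
    into predicted methylation in a hard-to-access target tissue (for example
    atrium or artery). Implements per-probe linear and epsilon support-vector
    regression calibration models, Illumina beta-value preprocessing (beta
    recomputation from intensities, detection-p and bead-count masking,
    quantile normalization, Infinium II to Infinium I alignment, SNP-probe and
    extreme-probe filtering), leave-one-family-out and leave-one-sample-out
    cross-validation with squared-correlation and mean-absolute-error
    accuracy reports, a multi-probe extension, sample-size experiments, and
    downstream-utility analyses (outcome association, effect-size bias
    comparison, hierarchical clustering), together with a synthetic paired
    beta-matrix generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    e1071,
    limma,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
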