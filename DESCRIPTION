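Package: ctiq
Title: Objective CT Image Quality from Edge Profiles, Noise Maps and Dose Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Observer-independent image-quality evaluation for computed tomography
    slices in Hounsfield units: perpendicular edge-profile extraction across a
    marked tissue border with per-profile baselines and steepest three-point
    slope, local noise estimation as the minimum of a sliding-window standard
    deviation map after edge exclusion and second-order polynomial detrending,
    and the derived signal-to-noise and contrast-to-noise ratios. Companion
    tools normalize dose-length product to a reference scan length, convert to
    effective dose with ICRP body-region factors, and compute reader-agreement
    and group-comparison statistics (two-way mixed consistency ICC, Cohen's
    kappa, Mann-Whitney, Welch t, Kolmogorov-Smirnov normality screening).
    A synthetic phantom generator with exact ground truth makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
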