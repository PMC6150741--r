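Package: texrep
Title: Test-Retest Repeatability of MR Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of 46 global and local-regional texture features
    (first-order histogram, fractal, gray-level co-occurrence, difference,
    run-length, zone-size and neighborhood gray-tone difference matrices)
    from segmented tumor volumes on T2-weighted MR images, and assessment of
    their day-to-day test-retest repeatability with Bland-Altman limits of
    agreement, the within-subject coefficient of variation and the
    repeatability coefficient. Includes a synthetic phantom generator that
    emulates paired test-retest tumor studies with controllable texture
    coarseness, within-subject intensity noise and region-of-interest
    re-delineation jitter, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
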