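Package: tangmorph
Title: Outline Morphometrics of Tanged Stone Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Elliptical Fourier analysis of closed tool outlines with
    translation, area-based size, and best-fitting-ellipse rotation
    standardization; principal-component shape spaces with extreme-shape
    reconstruction, external-sample projection and confidence ellipses;
    classical morphometric statistics for lithic reduction studies (Welch
    comparisons of tip and tang lengths, size regressions of shape scores,
    major-axis allometry with a bootstrap isometry test, score spread by
    length quantile, cumulative type curves); and a parametric generator of
    tanged-tool silhouettes with a staged resharpening simulator that
    provides ground truth for every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
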