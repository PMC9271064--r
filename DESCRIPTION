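Package: prolifmap
Title: Biophysical Proliferation Mapping of Tumor Response from Serial MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts serial diffusion-weighted and dynamic contrast-enhanced
    breast MRI into tumor cellularity maps, inverts a mechanically coupled
    reaction-diffusion growth model on a triangular finite-element mesh to
    estimate spatially resolved tumor proliferation rates between imaging
    time points, summarizes the proliferation maps with histogram metrics,
    and correlates those metrics with residual cancer burden. Includes a
    synthetic phantom generator so the full pipeline is exercisable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
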