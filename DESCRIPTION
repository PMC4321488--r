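Package: serialdx
Title: Pre-Merging Diagnostics for Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Diagnostics for serial diffraction experiments before merging:
    symmetry-aware clustering of per-frame unit cells with a Niggli-cone G6
    distance, laboratory-frame visualization of crystal orientation bias with
    a Bingham uniformity test, and per-frame 'pseudo-Wilson' fits of log
    partial intensity against squared scattering vector to detect multiple
    crystal forms, orientation bias and mis-indexed frames. Includes a native
    JSON frame format, a reader for a subset of the CrystFEL stream format,
    CSV reflection tables, and a synthetic dataset generator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
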