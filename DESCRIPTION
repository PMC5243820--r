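Package: canopyefd
Title: Elliptic Fourier Analysis of Plant Canopy Outlines
Version: 0.1.0
Authors@R: person("Canopy", "Morphometrics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for quantifying plant canopy shape from top-down RGB
    photographs. Segments the canopy from the soil background in HSV colour
    space, cleans and fills the binary mask, traces the closed outer outline,
    chain-codes it and expands it into elliptic Fourier descriptors (EFD).
    Descriptors can be truncated by a reconstruction-error criterion,
    standardized to be invariant to size, rotation and contour starting point,
    and used to recover traditional morphometric traits (aspect ratio,
    roundness, circularity, solidity). Shape diversity is summarized through
    per-group coefficients of variation, Tukey-fence outlier flags, PCA of the
    standardized coefficients with per-group convex-hull areas, and
    broad-sense heritability from randomized complete block trait tables.
    A synthetic-data module generates lobed canopy-like images with ground
    truth so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: grDevices, stats, utils, tools, png, jpeg, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
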