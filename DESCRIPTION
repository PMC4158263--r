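Package: nsctfusion
Title: Multimodal Medical Image Fusion in the Nonsubsampled Contourlet Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fusion of registered pairs of single-channel medical images
    (e.g. CT/MRI or MR-T1/MR-T2) in the nonsubsampled contourlet transform
    (NSCT) domain. The shift-invariant decomposition keeps every subband at
    the input size; low-frequency coefficients are selected by phase
    congruency, a contrast- and brightness-invariant feature measure, and
    high-frequency coefficients by local Log-Gabor filter-bank energy. An
    average-maximum baseline rule, an objective evaluation suite (standard
    deviation, edge-based similarity Q^AB/F, mutual information, cross
    entropy, spatial frequency, PSNR), a deterministic multimodal phantom
    generator, and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
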