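Package: glidekymo
Title: Kymograph Velocimetry and Motility Analysis for Gliding Diatoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intracellular actomyosin motion relative to a gliding
    raphid diatom from dual-channel time-lapse fluorescence movies. The
    pipeline tracks the two chloroplast autofluorescence landmarks to recover
    the cell's centre, long-axis angle and velocity; registers the GFP channel
    into the co-moving cell frame; builds maximum-projection kymographs with
    Fourier notch filtering of horizontal interference stripes; estimates
    myosin spot velocities from kymograph trace orientations (Fourier
    components orientation histograms and manual segments); and summarises
    population gliding motility from low-magnification brightfield movies.
    A ground-truthed synthetic movie generator makes every stage testable
    without raw imaging data, and closed-form low-Reynolds drag estimates
    support the force-balance argument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
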