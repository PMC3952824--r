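Package: resectrack
Title: Single-Cell Quantification of DNA Double-Strand-Break Resection
    from Live-Cell Fluorescence Movies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses dual-channel fluorescence time-lapse
    movies of ParB/parS-labelled chromatin loci flanking an
    endonuclease-induced DNA double-strand break in budding yeast.
    Provides a synthetic-microscopy generator with ground truth
    (truncated-Gaussian cleavage times, two-phase resection front,
    free-to-confined mobility switching, photobleaching background and
    camera noise), native spot detection and nearest-neighbour track
    linking, background-normalized focus-intensity traces with
    focus-loss calling, mean-square-displacement analysis with
    diffusion-coefficient estimation from the short-lag slope, and
    resection kinetics (loss-time distributions, resection durations
    and speeds for the slow and fast phases, and the repair-commitment
    delay between genotypes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tiff, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, CellBiology, Software, Visualization
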