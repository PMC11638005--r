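Package: slimcount
Title: Single-Molecule Stoichiometry, Periodicity and Photophysiology
    Analysis for Slimfield Microscopy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the oligomeric state of fluorescently tagged membrane
    protein complexes from Slimfield single-molecule photobleaching data.
    Provides a ground-truth simulator for photobleaching intensity traces and
    rendered image stacks, diffraction-limited spot detection with
    disc/annulus background-corrected photometry, nearest-neighbour track
    linking, single-fluorophore brightness calibration from terminal blink
    steps, kernel-density stoichiometry distributions with peak finding, and
    inverse-square-root-weighted inter-peak interval analysis reporting the
    oligomer periodicity with a bootstrap confidence interval. Also implements
    the standard chlorophyll-fluorescence parameters (NPQ, Y(II), Fv/Fm, qL,
    fast-relaxing NPQ) and electrochromic-shift proton-motive-force analysis
    (PMF, gH+, vH+, deltapH/deltaPsi partitioning), plus culture growth-rate
    and total-chlorophyll calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
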