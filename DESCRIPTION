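Package: hflpolar
Title: Henle Fiber Layer Thickness and Macular Phase Retardation Analysis
Version: 0.1.0
Authors@R:
    person("Macular", "Imaging Toolkit Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Quantifies the relationship between Henle fiber layer (HFL)
    thickness measured with directional optical coherence tomography (OCT)
    and macular phase retardation measured with scanning laser polarimetry
    (SLP). Provides a polarization-optics forward simulator (Jones-calculus
    composition of the radially oriented HFL retarder with a residual
    corneal retarder) that generates SLP retardation maps and directional
    OCT boundary traces with known ground truth, an OCT stage that combines
    opposite pupil-offset boundary traces into four-meridian thickness
    profiles, an SLP stage that localizes the macular center and extracts
    annular intensity statistics (ring means and the double-frequency
    macular-cross sinusoid amplitude), and a statistical layer with
    per-subject Pearson correlation, Fisher-Z cohort averaging, per-ring
    coefficients of variation, and Mann-Whitney cohort comparisons. A
    command-line pipeline orchestrates simulation, both imaging stages, and
    the statistics into a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
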