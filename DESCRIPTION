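Package: torsometry
Title: Transverse Cross-Section Asymmetry Analysis of 3D Torso Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Radiation-free surface morphometry of the human torso for
    scoliosis assessment. Extracts transverse cross-sections of a closed 3D
    torso surface mesh at the vertebral levels C7 to L5, converts each
    contour to a centroid-origin polar representation aligned on the
    spinous-process dip, and quantifies bilateral shape asymmetry through a
    left-right coefficient of determination of normalized contour radii,
    triangle-fan sector area asymmetries, and vertical distance profiles
    from an approximated vertebral-body line. Includes a parametric
    synthetic torso generator with known ground truth (dip position, rib-hump
    side, amplitude and apex level) so the full pipeline is testable without
    patient scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
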