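Package: ivctrack
Title: Active Shape-Model Estimation and Tracking of Vessel AP-Diameter in
    Ultrasound Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic measurement and frame-to-frame tracking of the
    anterior-posterior (AP) diameter of a vessel cross-section (typically the
    inferior vena cava) in B-mode ultrasound image sequences.  Three
    region-based parametric active-shape trackers are provided: an active
    circle baseline, an active ellipse driven by closed-form conic
    least-squares refitting, and an active rectangle whose height models the
    AP-diameter directly and whose width is annealed from 15 to 3 pixels.
    A synthetic speckle-phantom generator (convex vessel cross-sections with
    respirophasic collapse, Rayleigh multiplicative speckle, acoustic
    shadowing and boundary dropout) supplies ground-truthed test sequences,
    and an evaluation module computes RMS error, maximum absolute error,
    Pearson correlation, average position error and error distributions
    between estimated and reference AP-diameter tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
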