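Package: usrsc
Title: Reverse Scan Conversion and Field-of-View Geometry for B-Mode Ultrasound Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering the acquisition-grid (pre-scan-conversion)
    representation of B-mode ultrasound display frames. Estimates the
    field-of-view geometry of a convex or sector probe (apex position,
    transducer radius, opening angle, imaging depth) from a scan-converted
    display image via Hough-transform boundary detection, and resamples
    between the polar acquisition grid and the Cartesian display raster with
    bilinear interpolation (forward digital scan conversion and its reverse).
    Includes a speckle phantom generator with known ground-truth geometry, a
    batch builder for fixed-size training images, and a discrete-event
    simulator of frame-synchronous versus frame-asynchronous scheduling of a
    classification pipeline interleaved with image rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
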