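Package: afmtangent
Title: Tip Radius and Young's Modulus from Single AFM Force-Indentation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Simultaneous calibration of the spherical indenter radius and the
    sample Young's modulus from a single atomic force microscopy (AFM)
    force-indentation curve. Implements the exact Sneddon spherical contact
    model, its polynomial approximation for deep indentation, and the
    tangent-line method: the tangent to the force-indentation curve at
    maximum depth has an indentation-axis intercept that depends only on the
    depth-to-radius ratio, so the tip radius can be recovered without knowing
    the modulus, and the modulus then follows from the force-axis intercept.
    Includes contact-point detection for raw piezo/deflection curves, a
    synthetic-curve generator with known ground truth, lookup-table and
    inverse-map utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
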