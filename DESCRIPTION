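Package: wellcount
Title: Particle and Cell Counting from Microwell Array Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Digital counting of microparticles and cells with microwell
    arrays. Detects circular microwells in panel micrographs by a
    radius-bounded Hough transform, reconstructs the full rectangular well
    lattice from partial detections, classifies wells as occupied or empty
    from the bimodal distribution of per-well mean intensity, and converts
    the occupied fraction into a number density (particles per microliter)
    by Poisson statistics with Wilson or Clopper-Pearson confidence
    intervals. Includes a synthetic micrograph generator with known ground
    truth (bright-field and fluorescence modalities, aggregation, noise,
    illumination gradients) and design-space simulators relating confidence
    interval width to well count and measurable density range to well
    volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
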