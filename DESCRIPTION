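Package: traysow
Title: Machine-Vision Monitoring of Pot-Tray Seeding Performance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the seeding performance of hybrid-rice pot trays from
    production-line camera frames. Frames showing a tray beginning or end are
    gated out with a line-segment detector, image tilt is estimated from
    near-horizontal grid edges and removed by an affine rotation, grid and
    seed pixels are segmented by fixed hue thresholds in the HSL colour model,
    gridline pixel coordinates are located from projection profiles, the
    10 x 13-cell region of interest is split into per-cell pieces, empty
    cells and the missing rate are computed after a 30-pixel contour-area
    filter, and seeds in touching clusters are counted by a small 3-6-1
    feed-forward network on contour shape features (area, perimeter, shape
    factor). Includes a synthetic tray-image generator with exact ground
    truth so the whole pipeline is testable without production imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
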