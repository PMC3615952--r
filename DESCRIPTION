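Package: rhizotrack
Title: Slice-Tracking Segmentation of Plant Root Systems in X-Ray Micro-CT Volumes
Version: 0.1.0
Authors@R:
    person("rhizotrack", "developers", email = "rhizotrack@example.org",
           role = c("aut", "cre"))
Description: Extracts plant root systems from X-ray micro-computed tomography
    image stacks by tracking root cross-sections slice to slice with a
    narrow-band level-set segmentation driven by an adaptive grey-level
    appearance model.  A backward-looking step detects upward-growing
    (plagiotropic) laterals, which are recovered by alternating-direction
    tracking passes.  Computes whole-root-system architectural traits
    (voxel volume, iso-surface area, maximum width via the minimum
    enclosing circle, convex-hull volume via QuickHull with Monte Carlo
    integration, upward-growing fraction, growth-direction changes) and
    ships a synthetic soil-column phantom generator with voxel-level
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
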