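Package: tomomontage
Title: Acquisition Planning, Dose Simulation and Tile Processing for
    Montage Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for beam-image-shift montage cryo-electron tomography:
    static acquisition geometry (camera frame, beam footprint, tile grids,
    grouped dose-symmetric tilt schemes, focus/tracking placement),
    Archimedean-spiral translational offsets for dose spreading with
    tilt-angle adjustment and field-of-view clamping, a per-voxel electron
    dose simulator on a stage canvas with uniformity and overdose
    statistics, readers and writers for SerialEM-dialect acquisition
    metadata (mdoc files, acquisition macros, per-tilt piece-coordinate
    lists) and MRC image stacks, a two-path processing pipeline that sorts
    montage frames into per-tile tilt series and stitches per-tilt montages
    by coordinate priors plus cross-correlation refinement, Fresnel-fringe
    cutoff calibration from gain-normalized beam images, and dose-based
    curation of sub-tomogram particle tables.  Deterministic synthetic-data
    generators provide phantoms, tilted montage datasets, fringed beam
    images and particle tables for testing the full workflow without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
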