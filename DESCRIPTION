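Package: odorgaze
Title: Olfactory Modulation of Motion Vision in Drosophila: System
    Identification, Plume-Tracking Metrics, and Calcium Epoch Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how appetitive odor modulates
    visually guided flight behavior and wide-field motion-sensitive neurons in
    Drosophila. Implements white-noise estimation of the yaw optomotor impulse
    response from rigid-tether wingbeat recordings with double-exponential
    kernel fits and paired odor/water gain comparisons; three-phase odor
    plume-tracking metrics (detection, acquisition, continuous tracking) from
    magnetic-tether heading traces with group statistics; and epoch-structured
    calcium-imaging analyses (dF/F extraction, per-epoch peak statistics,
    odor-pairing rank-sum tests, QC exclusion) together with visual tuning fits
    (azimuthal receptive field, bar width, direction, temporal frequency).
    Seeded synthetic-data generators emulate all three experiment types so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    rlang,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
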