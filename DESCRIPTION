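Package: aggrescope
Title: Microscale Oxygen and Microbial Colony Dynamics in Model Marine Snow Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-computation pipeline for time-lapse microscopy of model
    marine-snow particles colonized by facultatively denitrifying bacteria.
    Provides per-particle, radially zoned two-endmember calibration of
    oxygen-quenched nanosensor fluorescence (Stern-Volmer inversion),
    particle edge detection and distance-to-edge geometry, diatom exclusion
    by elongation shape factor, microcolony segmentation and backtracking
    across frames, growth-phase (diauxic lag) decomposition of colony area
    trajectories, oxygen-exposure area fractions, radial biomass and
    gene-expression profiles, and depth translation of time series via an
    imposed sinking speed. A synthetic-scene generator with known ground
    truth (quasi-steady reaction-diffusion oxygen fields, rendered
    brightfield and sensor channels, bulk chemistry series) makes every
    stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
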