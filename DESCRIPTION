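Package: narpump
Title: Analysis of Light-Driven Sodium-Pump Rhodopsin Photocurrents and
    Optogenetic Silencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for characterizing light-driven Na+-pump rhodopsins
    (NaRs) used as optogenetic silencers. Extracts peak and steady-state
    photocurrent densities and inactivation ratios from whole-cell recordings,
    fits irradiance-response curves with Michaelis-Menten and
    suppression-subtracted composite models, estimates voltage-dependence
    slopes of normalized I-V relationships and irradiance-corrected relative
    action spectra, quantifies membrane targeting with a 14-lag
    cross-correlation overlapping index on confocal line profiles, analyses
    current-clamp silencing experiments (spike detection, 1-s time-zone firing
    rates, light/dark ratios, exact rank tests), classifies ion-transport
    activity from pH-assay slopes with an H+/Na+ flux-ratio bound, and builds
    transmembrane-domain chimeras between rhodopsin parents. Includes seedable
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
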