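Package: corticostate
Title: Behavioral Correlation States from Wide-Field Optical Mapping of Mouse Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous wide-field calcium imaging and
    intrinsic optical (reflectance) imaging of the mouse dorsal cortex.
    Converts dual-wavelength reflectance to oxy-/deoxy-hemoglobin concentration
    changes via the modified Beer-Lambert law, corrects raw red-shifted
    indicator fluorescence for time-varying hemoglobin absorption, performs
    data-driven bilateral functional parcellation by correlation-distance
    k-means, computes moving-window interregional correlation maps, and
    decomposes them into behavioral correlation states (locomotion onset,
    sustained locomotion, offset, initial rest, sustained rest) by
    non-negative least squares, together with locomotion-bout detection,
    pupil/whisker-derived behavioral traces, arousal association analyses and
    the accompanying nonparametric statistics. Includes a ground-truthed
    synthetic session generator emulating state-switching cortical dynamics,
    neurovascular coupling and the optical forward model, so the full chain is
    testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
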