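Package: coaflow
Title: Doppler-Echocardiography-Driven Boundary Conditions for
    Patient-Specific CFD of Aortic Coarctation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preprocessing pipeline turning digitized Doppler
    transthoracic echocardiography velocity waveforms and vessel
    cross-section geometry into mass-consistent volumetric-flow boundary
    conditions for computational fluid dynamics of coarctation of the
    aorta. Provides waveform smoothing and cardiac-period normalization,
    simplified-Bernoulli pressure estimates, velocity-to-flow conversion,
    three flow-split regimes for complete, partial and hypothetical
    healthy datasets, coarctation-severity metrics from cross-section
    contours or area/perimeter pairs, ready-to-run OpenFOAM case file
    generation, a grid-independence assessment of sampled solver output,
    and a seeded synthetic-patient generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    signal
Config/testthat/edition: 3
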