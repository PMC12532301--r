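Package: RayleighMatch
Title: Rayleigh-Match Prediction and Anomaloscope Reliability Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models Rayleigh matching on LED-based anomaloscopes. Synthesizes
    primary spectral power distributions and cut-on filter transmittances,
    constructs normal cone fundamentals from a visual-pigment nomogram and
    anomalous (protanomalous/deuteranomalous) fundamentals by shifting the
    photopigment template on a frequency (wavenumber) abscissa after removing
    pre-receptoral lens and macular absorption, and predicts the red/green
    mixture setting at which the cone-excitation ratio of the mixture field
    equals that of the amber reference field. Includes a synthetic-cohort
    generator for repeated anomaloscope sessions on multiple instrument
    models, and a reliability-analysis layer (session summaries, test-retest
    and cross-instrument correlations, phenotype classification agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, graphics
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
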