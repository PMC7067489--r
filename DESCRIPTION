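Package: itpcflow
Title: Spectral Profiling of Impulse-Evoked Intracranial Auditory Responses
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for stereotactic EEG responses to brief
    auditory stimuli: intertrial phase coherence (ITPC) spectra obtained by
    Morlet wavelet decomposition and one-oscillatory-cycle time averaging,
    extraction of the two highest noncontiguous spectral peaks, leave-one-out
    cross-validated hemisphere classification by template similarity, and
    non-negative matrix factorization of ITPC spectra into prototypical
    spectral components. Includes a synthetic cohort generator producing
    phase-locked damped oscillations over 1/f background noise, bipolar
    referencing, auditory evoked potential (AEP) based contact selection,
    and the nonparametric and parametric group statistics used to compare
    hemispheres.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
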