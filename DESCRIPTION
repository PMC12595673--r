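Package: assrtools
Title: Auditory Steady-State Response and Spontaneous ECoG Oscillation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel electrocorticogram (ECoG)
    recordings of auditory steady-state responses (ASSRs) in rodents:
    multitaper power spectral density of spontaneous activity with standard
    band summaries, Morlet-wavelet time-frequency metrics (phase-locking
    factor, induced power ratio, evoked power, harmonic responses),
    within-animal drug-effect deltas, normality-routed two-sample and paired
    statistics, and two-way mixed-effects absolute-agreement intraclass
    correlation for test-retest reliability. Includes a synthetic cohort
    generator with known ground-truth parameters (von Mises trial phases,
    1/f-plus-band spectral backgrounds, hierarchical animal/day/session
    variance components) so the whole pipeline can be validated by parameter
    recovery, plus EDF and binary epochs-bundle I/O.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
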