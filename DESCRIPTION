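Package: sleepcoh
Title: Brain-State, Spindle and Imaginary-Coherence Analysis of Rodent Multi-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing chronic multi-channel rodent EEG recordings:
    hypnogram bout statistics with artifact and seizure-time exclusion,
    spike-and-wave-discharge detection from harmonic structure in the power
    spectrum, envelope-threshold sleep-spindle detection with multi-electrode
    grouping, per-epoch multitaper log-power spectra, distance-thresholded
    imaginary-coherence spectra with Fisher-z averaging, spindle-locked Morlet
    coherograms with a high-connectivity bin statistic, and two-sided
    cluster-corrected permutation tests. Includes a synthetic EEG generator
    with known ground truth (hypnogram, planted spindles, discharges,
    artifacts, lagged coupling) for end-to-end validation, plus minimal EDF
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
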