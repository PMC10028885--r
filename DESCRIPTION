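Package: aancolumn
Title: Biophysical Neocortical Column Modeling of the Auditory Awareness
    Negativity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a reduced two-layer neocortical column of
    conductance-based pyramidal and basket neurons, activated by sequences
    of proximal (feedforward) and distal (feedback) evoked drives, and
    compares its primary current dipole against source-localized auditory
    evoked responses.  The package provides laminar decomposition of the
    dipole, simulated laminar local field potentials, spike rasters and
    burst statistics, RMSE-based fitting of drive parameters to target
    waveforms, alternative circuit variants (perisomatic GABA-B
    inhibition, reduced and proximal-distal-proximal drive sequences),
    and a synthetic-data generator that emulates grand-average evoked
    source waveforms and the auditory oddball detection paradigm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
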