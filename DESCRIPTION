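Package: engramr
Title: Detection of Reverberations and Engrams in Neuronal Network Recordings
Version: 0.1.0
Authors@R:
    person("Engramr", "Developers", email = "engramr@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for detecting reverberations and engrams of
    induced firing patterns in neuronal network activity recordings from
    calcium imaging. Provides a synthetic-data generator emulating a
    test-pulse / prestimulation / stimulation / poststimulation paradigm
    with known ground truth, spike inference from fluorescence traces with
    slow-onset (glial) event exclusion, paradigm-segmented inter-spike
    interval histogram statistics with frequency-component matching, a
    minimal bidirectional recurrent sequence classifier trained on the
    stimulation epoch and scanned over recordings in a sliding window to
    map full-pattern engrams, and population-level excitatory/inhibitory
    and frequency-component overlap analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
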