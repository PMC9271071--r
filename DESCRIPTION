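Package: twocap
Title: Population Representations of Drinking Decisions in Cued-Access Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for prefrontal population recordings from
    two-way conditioned access protocol (2CAP) alcohol drinking sessions.
    Infers the behavioral seeking-state change point and per-trial approach
    initiation from snout tracking, preprocesses spike trains (100 ms bins,
    adaptive Gaussian smoothing, peri-event alignment, z-scoring), runs
    group-matched subsampled principal component analysis with stability
    selection, quantifies representation strength as Euclidean separation
    between trial-type trajectories across stable components, classifies
    units as putative excitatory or inhibitory from waveform depolarization
    delays, and ships a synthetic session generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
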