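Package: quinex
Title: Quinone Exchange Pathway Analysis for Membrane-Protein Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of plastoquinone/plastoquinol exchange between
    a membrane-embedded protein complex (photosystem II) and the surrounding
    thylakoid membrane. Provides region-based state labelling with hysteresis,
    detection of channel passages, flip-flop and binding-site unbinding events,
    per-channel flux tables with standard errors over monomer replicates,
    exchange-cavity occupancy statistics, 3D occupancy density grids with
    OpenDX export, a continuous-time Markov chain trajectory generator with
    exact ground-truth event logs for validation, and an adaptive-respawn
    harness for enriching rare events in short simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
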