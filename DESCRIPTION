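Package: kuradbs
Title: Plasticity-Endowed Kuramoto Simulation of Deep Brain Stimulation
    Withdrawal and Insertion
Version: 0.1.0
Authors@R:
    person("Kuradbs", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a network of Kuramoto phase oscillators whose
    pairwise coupling strengths are fixed by long-term potentiation and
    depotentiation rates, driven by a rectangular-pulse deep-brain
    stimulation (DBS) train. Provides block-structured ON/OFF stimulation
    protocols (chronic withdrawal/renewal and de novo insertion),
    synchronization quantification by grand-average phase-locking value
    (PLV), baseline-normalized percentage change, replicate orchestration
    with deterministic seeding, and JSON/CSV input-output suitable for
    reproducible in silico experiments on stimulation dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
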