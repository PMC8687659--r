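Package: infoflow
Title: Information Transfer and Exploration-Exploitation Dynamics in Paired Homing Flights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify leader-follower dynamics in pairs of homing
    pigeons from GPS trajectories. Flight tracks are encoded as binary
    clockwise/counterclockwise rotation series, from which plug-in transfer
    entropy, local (pointwise) transfer entropy, and predictive power are
    estimated per flight. Includes surrogate-pairing significance testing,
    front/back leadership segmentation from the projected inter-bird
    distance, exploration-exploitation labelling of routes against baseline
    trajectories, robust trend estimation, and a correlated-random-walk
    simulator of paired flights and transmission-chain experiments with
    known ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
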