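Package: betaburst
Title: Detection and Local/Global Classification of Beta Bursts in
    Multichannel Field Potentials
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting transient beta-band oscillation bursts in
    multichannel cortical and subcortical local field potentials, splitting
    cortical burst epochs into spatially local versus array-wide global
    events with a Gaussian-mixture channel-fraction threshold, and
    quantifying their spatial clustering (permutation shuffle null), spike
    entrainment (resultant vector with rate-matched shuffle calibration),
    burst-conditioned firing statistics, linear population-dynamics
    predictability, and relation to reach-to-grasp behavior and a
    recovery index.  Includes a ground-truthed synthetic-session generator
    so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    rhdf5
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
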