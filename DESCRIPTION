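Package: flocknet
Title: Foraging Social Networks from RFID Feeder Visit Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how an experimental manipulation of local
    population density at paired selective RFID feeders changes foraging
    social structure and novel-patch discovery in wild birds. Detects
    non-overlapping flocking events from time-stamped antenna reads with a
    univariate Gaussian mixture model, builds simple-ratio-index association
    networks, computes global and individual network metrics, estimates
    Newman's weighted assortativity with an edge jackknife and a
    label-permutation null, runs node-permutation significance tests for
    period-by-treatment contrasts, and scores patch-discovery trials
    (probability, latency, tie-grouped arrival order). Includes a seeded
    stochastic colony simulator producing visit logs with planted flocking
    events so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    glmmTMB,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
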