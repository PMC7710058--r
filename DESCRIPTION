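Package: satkit
Title: Simulation and Analysis of Automated Homecage Sensory Association Training
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for automated homecage sensory association
    training (SAT) experiments in which a multiwhisker air-puff stimulus is
    paired with a water reward on self-initiated trials. Provides a
    discrete-event simulator of the trial controller (Bernoulli trial
    assignment, random pre-stimulus delays, fixed actuation timings, lockout
    enforcement, tab-separated event logs), a parametric synthetic-mouse agent
    with associative learning, novelty suppression, intensity-dependent
    detection and dropout, the anticipatory-licking analysis pipeline
    (100 ms lick debouncing, alignment to air-puff onset, the 700-1000 ms
    anticipatory window, 4-hour binning, the L_w - L_b performance metric and
    last-20%-of-trials criterion), whisker motion-energy estimation with a
    Gabor filter bank, whisking-bout detection, and the nonparametric group
    statistics used to compare training conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, TimeCourse, CellBasedAssays
RoxygenNote: 7.3.3
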