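Package: quietrack
Title: Simulation and Automated Tracking of Cellular Quiescence from
    Dual-Reporter Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying spontaneous quiescence (G0) and
    asynchronous proliferation-quiescence decisions in single cells from
    two-channel fluorescent cell-cycle reporter movies (a G0 reporter such
    as mVenus-p27K- together with the G0/G1 FUCCI reporter mCherry-hCdt1).
    Includes a stochastic single-cell lineage and reporter-kinetics
    simulator with ground truth export and two-channel movie rendering;
    frame-by-frame cell segmentation; frame-to-frame optimal-assignment
    tracking with gap closing and division detection; hysteresis-based
    classification of reporter traces into cell-cycle state segments with
    quiescence calls; and lineage-level analysis of daughter-pair fate
    synchrony, dwell-time distributions and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    clue,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
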