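Package: plateOMR
Title: High-Throughput Plate-Based Larval Activity and Optomotor Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-well plate behavioral imaging of
    zebrafish larvae: partitions user-outlined plate rows into per-well
    regions, detects moving larvae by consecutive-frame subtraction and
    thresholding, scores per-larva activity (larval movement per interval)
    and the even-minus-odd (E-O) optomotor response to moving-line stimuli,
    and performs the binned chi-squared group statistics with Bonferroni
    correction and median-p summaries across repeat experiments. Includes a
    stochastic larva/stimulus simulator that renders synthetic frame series
    with recoverable ground truth, so every pipeline stage can be validated
    without the physical imaging rig.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    parallel,
    tools,
    png,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jpeg,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
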