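Package: cfpsopt
Title: Active-Learning Optimization of Cell-Free Protein Synthesis Buffers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop Design-Build-Test-Learn optimization of
    cell-free protein synthesis (CFPS) reaction buffers on acoustic
    liquid-handling platforms. Provides discrete Latin-hypercube sampling over
    dispenser-legal volume grids, 384-well source/destination plate layout
    design with dead-volume accounting, Echo-style transfer-list generation
    with volume splitting, plate-reader import with cross-plate calibration
    and fold-change yield computation, a Gaussian-process surrogate with
    Expected-Improvement acquisition and Cluster-Margin batch selection, and
    a simulated yield landscape for benchmarking the full loop without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
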