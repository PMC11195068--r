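Package: fearsync
Title: Quantifying Fear Synchrony in Mouse Dyads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of synchronized conditioned
    freezing in pairs of mice. Converts frame-indexed freezing-bout
    annotations into per-frame binary traces, computes chance-corrected and
    virtual-dyad-corrected synchrony scores, decomposes dyad behavior into a
    four-state sequence with transition and two-step motif ("follow" and
    "retroact") counts, and provides group-level statistics (fear buffering,
    freezing equalization, balanced partner correlations, top/bottom
    synchrony splits). A coupled two-animal simulator with tunable follow and
    retroact coupling generates realistic synthetic cohorts so every stage of
    the pipeline can be validated without behavioral recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
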