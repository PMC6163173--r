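Package: coexpnet
Title: Weighted Gene Co-Expression Network Module Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and analysis of signed weighted gene co-expression
    networks from positive-valued expression compendia. Implements soft-threshold
    power selection by the scale-free topology criterion, topological overlap,
    average-linkage clustering with a documented dynamic tree cut variant,
    module eigengenes by singular value decomposition, half-sample connectivity
    stability resampling, relative standard deviation profiling, module-condition
    association, a higher-order eigengene meta-network, and log-space
    hypergeometric over-representation statistics with Benjamini-Hochberg
    adjustment (gene-set, positional, and set-overlap variants). Includes a
    planted-module synthetic expression generator so the full pipeline is
    testable without external downloads, plus TSV/GMT/BED readers and writers
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
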