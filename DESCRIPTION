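Package: longnet
Title: Three-Level Graph Analysis of Longitudinal Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional connectivity networks from regional
    resting-state time series and analyses them at three organizational
    levels: global topology (cost, efficiency, path length, clustering,
    strength, modularity), modular structure (Newman spectral partitioning of
    a group-mean backbone network, intra- and inter-module connectivity
    strength) and nodal strength. Includes time-series preprocessing
    (band-pass filtering, framewise-displacement scrubbing, nuisance
    regression with the 24-parameter motion expansion), a two-group by
    two-session mixed ANOVA with interaction and simple-effect tests, and a
    synthetic-cohort generator with planted modular covariance for
    end-to-end validation of the pipeline without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    yaml,
    mclust,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
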