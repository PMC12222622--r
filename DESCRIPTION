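Package: divpart
Title: Multiscale Selection Partitioning of Temporal Diversity Change in
    Metacommunities
Version: 0.1.0
Authors@R:
    person("divpart", "maintainers", email = "divpart@example.org",
           role = c("aut", "cre"))
Description: Partitions census-to-census change in the Shannon diversity
    (and its Hill-number transform) of a hierarchical metacommunity into
    five additive mechanisms: selection among species, selection among
    habitats, selection among communities, transmission (the nonlinear
    response of diversity to shifts in relative abundance), and
    immigration into the region.  Includes a Poisson parametric bootstrap
    for empirical confidence intervals on every term, a synthetic
    metacommunity simulator with scale-specific fitness and scheduled
    immigration pulses, readers and writers for a tidy long-format count
    table, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
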