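Package: pressrecover
Title: Resistance, Resilience and Activity Dynamics of Microbiomes
    Under a Press Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing paired 16S rRNA / rRNA-gene amplicon time
    series from disturbance experiments. Partitions each sample into Total
    and Active communities using the rRNA:rRNA-gene ratio (with explicit
    phantom handling), computes alpha diversity, Bray-Curtis dissimilarity
    and its taxon-subset decomposition, principal coordinates ordination and
    beta dispersion, derives resistance and resilience indices of community
    structure over configurable recovery windows, and classifies taxa into
    disturbance-response categories (sensitive, transition, resilient,
    opportunist, immigrant). Includes a mechanistic mesocosm simulator with
    dormancy dynamics, a thermal niche filter, relic DNA and a dispersal
    event, emitting paired count tables with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    yaml,
    optparse
Config/testthat/edition: 3
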