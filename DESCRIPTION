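Package: traitshift
Title: Community-Weighted Mean Trait Change Under Climate Scenarios for Wetland Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for projecting climate-driven shifts in the
    functional composition of wetland plant communities. Occurrence records
    carrying a three-level abundance class are fitted with a presence-background
    maximum-entropy species distribution model per abundance class, the class
    probabilities are combined into a relative-abundance estimate, canopy height
    is converted to maximum potential biomass through allometric scaling, and
    per-cell community-weighted mean traits (continuous) and biomass-proportion
    profiles (categorical) are computed per vegetation layer and wetland type
    for current and scenario climates. Gaps in continuous traits are filled by
    Brownian-motion conditioning on a phylogeny, landscapes are partitioned into
    regions of similar community change with k-means, and a synthetic-data
    module generates landscapes, species, occurrences, traits and climate
    deltas with the statistical structure the analysis assumes, so the whole
    pipeline is testable without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
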