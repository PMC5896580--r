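Package: cytosim
Title: Forward Simulation of Adaptive Evolution in Cytoplasmic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based forward simulator for the accumulation of
    beneficial and deleterious substitutions in asexual cytoplasmic genomes
    (mitochondria, plastids, obligate endosymbionts) organised inside diploid
    host cells, compared against a free-living asexual null model. Hosts carry
    n genome copies, transmit b copies per gamete through a germline
    bottleneck, and inherit cytoplasmic genomes either uniparentally or
    biparentally; selection acts on host cells through additive fitness maps
    of the total beneficial and deleterious substitution load. The package
    provides the life-cycle engine (mutation, selection, gametogenesis,
    mating/repopulation), a matched free-living Wright-Fisher engine, and the
    analysis statistics used to characterise the dynamics: drift/selection
    phase decomposition, loss and regain probabilities, sweep slopes and
    coexisting-class counts (clonal interference), beneficial and deleterious
    ratchet events, a genetic hitchhiking index, and the adaptive-evolution
    ratio, together with replicate orchestration for full experiment grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
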