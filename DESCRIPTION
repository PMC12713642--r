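Package: phyllocore
Title: Stratified Core Microbiomes and Community Stability in
    Host-Environment Systems
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing vertically stratified host-environment
    microbiome systems such as litter-moss-soil profiles. Implements
    core-microbiome detection and its stratification into host-unique,
    host-enriched and environmental components via zero-inflated beta
    contrasts; Sloan's neutral community model with per-taxon partitioning
    against a confidence envelope; Herren-McMahon cohesion and
    co-occurrence network robustness; distance-based community structure
    statistics (Bray-Curtis, NMDS, PERMANOVA, beta-dispersion, Mantel);
    per-sample stability indicators (average variation degree, association
    strength); and piecewise path models evaluated with Fisher's C. A
    synthetic-data module generates habitat-structured communities with
    known ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vegan,
    picante,
    igraph,
    glmmTMB,
    car,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohesion.R'
    'core.R'
    'diversity.R'
    'io.R'
    'methods-AbundanceTable.R'
    'network.R'
    'neutral.R'
    'pipeline.R'
    'prep.R'
    'sem.R'
    'simulate.R'
    'stability.R'
    'structure.R'
    'utils.R'
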