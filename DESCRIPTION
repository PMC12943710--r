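Package: rhizonet
Title: Rhizosphere Microbiome Assembly, Co-Occurrence Networks and Soil
    Multi-Nutrient Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline linking rhizosphere soil multi-nutrient
    cycling (SMC) to microbial diversity, community assembly processes and
    cross-kingdom bacteria-fungi co-occurrence networks in pure versus mixed
    plantation designs. Implements the soil multifunctionality z-score index;
    alpha/beta diversity with PCoA and one-factor PERMANOVA; null-model
    assembly inference (beta-MNTD, beta-NTI, Bray-Curtis Raup-Crick, the
    five-process partition, modified stochasticity ratio) and the Sloan
    neutral community model; correlation-screened signed co-occurrence
    networks with cohesion, natural-connectivity robustness and Zi-Pi
    keystone classification; and driver models (permutation-importance
    random forests and recursive standardized path analysis). A synthetic
    study generator with controllable neutral versus selective assembly
    regimes provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    MASS,
    randomForest,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
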