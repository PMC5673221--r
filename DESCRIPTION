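Package: tgbsdm
Title: Target-Group Background Pseudo-Absence Strategies for Boosted
    Regression Tree Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares pseudo-absence generation strategies for presence-only
    species distribution models fitted with stochastic gradient boosted
    regression trees. Implements unweighted and weighted target-group
    backgrounds (with the p_k/a_k weighting that balances total pseudo-absence
    and presence weight) and random pseudo-absence replicates, a weighted
    Bernoulli boosting engine with stepwise cross-validated selection of the
    tree count, the full evaluation protocol (fold-level AUC and weighted
    deviance, true-skill-statistic threshold sweeps, a Shapiro-Wilk / Levene /
    t-test / Wilcoxon comparison cascade), model interpretation (relative
    influence, partial dependence, pairwise interaction sizes), suitability
    map discretization with class areas, Moran's I screening of occurrence
    grids, and a seeded virtual-species simulator so the whole study runs
    end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
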