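Package: taxrisk
Title: Taxonomic-Accumulation Features and Gradient-Boosted Disease Risk
    Scoring for 16S Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 16S rRNA OTU count tables into genus-level feature
    matrices by hierarchical taxonomic accumulation (each genus abundance
    augmented with geometrically down-weighted clade sums from family up to
    kingdom), and trains gradient-boosted tree models that score
    inflammatory bowel disease and colorectal cancer risk from stool
    microbiome profiles. Includes alpha/beta diversity with rarefaction,
    PCoA and PERMANOVA, two-group and multi-group differential-abundance
    statistics with Benjamini-Hochberg correction, repeated random-split
    cross-validation with ROC/AUC summaries and feature importance,
    cross-cohort (transfer) risk scoring with feature alignment, and a
    zero-inflated compositional cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
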