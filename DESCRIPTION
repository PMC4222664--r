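Package: repgeom
Title: Representational Geometry Analysis of Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing computational model representations to brain
    representations at the level of their representational dissimilarity
    matrices (RDMs). Implements RDM construction from feature matrices,
    Kendall tau-a RDM comparison with stimulus-label randomization and
    stratified stimulus-bootstrap inference, multi-subject noise-ceiling
    estimation, category-cluster model fitting and categoricality indices,
    noise equating between models and brain data, non-negative least-squares
    reweighting of component representations with stimulus crossvalidation,
    linear-readout categorization performance with category-orthogonalized
    permutation nulls, and a synthetic-data generator that emulates
    multi-model, multi-subject object-vision studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    pracma,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    arrow,
    knitr,
    rmarkdown
Config/testthat/edition: 3
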