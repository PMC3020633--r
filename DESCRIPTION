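Package: dcboot
Title: Parametric-Bootstrap Tests of Species-Tree Hypotheses by Deep
    Coalescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven structured-coalescent simulation of multi-locus
    gene trees under explicit demographic models (population splits,
    epoch-limited migration, lineage-specific effective sizes), scoring of
    gene trees against rival species trees by the minimum number of deep
    coalescences (extra lineages), and parametric-bootstrap evaluation of
    species-tree hypotheses from the empirical tail probabilities of the
    deep-coalescence count and the delta statistic (the difference in fit
    between two rival species trees).  Ships the fifteen demographic models
    of North American Limenitis admiral butterflies used to test whether
    the Batesian-mimetic lineages of Limenitis arthemis are monophyletic
    or whether mimicry was lost in L. a. arthemis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
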