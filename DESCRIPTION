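Package: stlta
Title: Local Trend Analysis with Fast Significance for Dependent Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local trend analysis (LTA) for pairs of biological time series
    such as OTU abundance or gene-expression profiles. Series are discretized
    into up/flat/down trend symbols, scored by the maximal co-trending aligned
    window (the local trend score), and assigned approximate p-values from a
    Brownian-motion extremum tail law whose variance is computed from Markov
    transition matrices fitted to the observed trend chains (STLTA). The
    i.i.d.-assumption variant (TLTA) and a permutation test are included, as
    are the stationary null-model simulators used to assess type I error
    calibration, and an all-pairs screening pipeline for wide abundance tables
    with prevalence filtering, linear interpolation of missing values and
    Benjamini-Hochberg false discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
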