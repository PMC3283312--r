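Package: wgdfrac
Title: Fractionation Statistics for Whole-Genome-Duplication Descendants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-parameter null model of post-whole-genome-duplication
    fractionation, the loss of duplicate genes by excision of geometrically
    distributed numbers of contiguous genes. Provides stochastic simulators of
    the one-sided and two-sided deletion processes on a pair of homeologous
    chromosomes, exact run-length and event-provenance statistics, a
    deterministic recurrence for the distribution of the number of deletion
    events per single-copy run as fractionation proceeds, estimation of the
    mean deletion length from observed run lengths via a simulated response
    surface, a rearrangement-survival correction for observed run lengths, and
    a scanner for analytical units (two-sided single-copy runs flanked by
    intact duplicate pairs) in annotated gene orders, together with a
    synthetic-genome generator for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
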