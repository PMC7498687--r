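Package: obulink
Title: Linking Biosynthetic Domain Diversity to Taxonomy in Amplicon Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing biosynthetic-domain amplicon surveys of
    microbial communities. Implements two-round greedy identity clustering of
    ketosynthase (KS) and adenylation (AD) domain amplicons into operational
    biosynthetic units (OBUs), formula-level diversity statistics (Chao1,
    rarefaction, Bray-Curtis, PCoA, PERMANOVA), a no-intercept linear screen
    that attributes OBUs to 16S-derived taxa, culturable-fraction recovery
    accounting, and a synthetic community generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
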