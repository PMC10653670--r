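Package: gardenscan
Title: Host Genomic and Gut Microbiome Dissimilarity Analysis for
    Common-Garden Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links host genomic dissimilarity to gut-microbiome
    dissimilarity in common-garden cross designs. Provides genetic
    (fractional allelic difference), Bray-Curtis, weighted UniFrac and
    body-size dissimilarity matrices; Mantel and partial Mantel
    permutation tests; a sliding-window genome scan with cross-metric
    peak calling; PERMANOVA, principal coordinates analysis and
    beta-dispersion statistics on distance matrices; a permutation-null
    random-forest population classifier; and a synthetic common-garden
    data generator (Mendelian crosses with zero-inflated negative
    binomial ASV counts and planted genomic effects) for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    randomForest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    vcfR,
    vegan,
    withr
Config/testthat/edition: 3
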