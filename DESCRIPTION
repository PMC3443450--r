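Package: sdmap
Title: Integrated Linkage Maps from Single-Dose Markers in Outcrossed F1
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of integrated genetic linkage maps for outcrossed
    F1 populations genotyped with dominant single-dose markers (AFLP, EST-SSR
    and retrotransposon-anchored fingerprints), as used for highly polyploid
    crops such as sugarcane. Provides segregation classification of D1/D2/C
    cross types with chi-square tests and Bonferroni filtering, maximum
    likelihood two-point recombination fraction and linkage phase estimation,
    co-segregation grouping by LOD and recombination thresholds, multipoint
    marker ordering with a four-state hidden Markov model fitted by EM,
    Kosambi map distances, assembly of homo(eo)logous groups from shared
    EST-SSR loci, Poisson goodness-of-fit tests for marker clustering,
    retrotransposon copy-number estimation from fingerprint band counts, and
    a population simulator with known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
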