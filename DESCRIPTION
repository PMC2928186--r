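Package: exdiv
Title: Distance Measures for Cross-Species Gene Expression Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares distance measures for gene expression divergence
    between orthologous genes of two species profiled across homologous
    tissues. Implements the relative-expression and binary transforms,
    Shannon expression entropy, Euclidean and correlation-based distances,
    and the generalized-average (GA) parametric family of binary
    dissimilarities (subsuming Simpson, Dice and Ochiai); provides
    moment-based selection of GA exponents, average-link clustering of
    cross-species tissue samples with homologous-pairing scoring, an
    empirical random-pair null for calling conserved ortholog pairs, and a
    synthetic two-species expression generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
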