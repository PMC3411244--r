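Package: shustring
Title: Alignment-Free Estimation of Nucleotide Diversity from Shortest
    Unique Substrings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates pairwise nucleotide diversity (pi) between two
    unaligned genomes from the length distribution of shortest unique
    substrings (shustrings). Shustring lengths are computed in near-linear
    time with a suffix-automaton matching-statistics index, and diversity is
    estimated either by maximum likelihood under a coalescent model of the
    shustring-length distribution (pi_d) or from the inverse mean shustring
    length (pi_m). Includes a sliding-window scanner with a missing-data
    heuristic, a two-lineage sequentially Markov coalescent simulator with
    recombination for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    generics,
    ggplot2,
    optparse,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
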