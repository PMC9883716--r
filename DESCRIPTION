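Package: phmmscore
Title: Correspondence Between Alignment Scoring Schemes and Pair Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts pairwise alignment scoring schemes (substitution
    matrix, affine gap scores, temperature) into equivalent pair hidden
    Markov models and back.  Solves for homogeneous letter probabilities,
    finds the uniform-length-probability temperature of a substitution
    matrix, classifies balanced length probability for gapped models,
    and computes feasibility limits on model parameters.  Provides
    maximum-score local and global alignment with affine gaps, Forward
    and posterior (column-reliability) calculations for two local
    pair-HMM topologies, mapping probabilities, hybrid alignment scores,
    and Gumbel calibration of hybrid-score statistics on simulated
    random sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
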