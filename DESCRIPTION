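Package: tandemscan
Title: Tandem Repeat Annotation with a Context-Sensitive Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and annotates tandemly repetitive regions in DNA/RNA
    sequences using a context-sensitive hidden Markov model whose repetitive
    states compare each letter to the letter one repeat period back, with
    explicit insertion/deletion offset states. Decoding uses a windowed
    Viterbi algorithm with relative emission likelihoods, producing scored
    repeat regions with P-values calibrated against random sequence,
    Jensen-Shannon-divergence based splitting of regions into subrepeats with
    canonically named repeat units, and shuffle-based false-discovery-rate
    parameter tuning. Includes seeded simulators for random sequence, mutated
    tandem repeats and split-detection benchmarks, plus FASTA input and
    BED/TSV/JSON output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
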