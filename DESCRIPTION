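Package: pairfold
Title: RNA Secondary Structure Prediction from Pairwise Score Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA secondary structure, including pseudoknots, by
    encoding a sequence as an L x L x 8 one-hot map of pairwise base
    relations, scoring all candidate base pairs with a residual
    convolutional network trained with intermediate mean-squared-error
    losses, and decoding the score matrix into a valid structure either by
    row-wise argmax or by maximum-weight matching (Blossom algorithm) on a
    duplicated graph that models unpaired bases as self-loops. Includes
    readers and writers for FASTA, CT, BPSEQ and pseudoknot-aware
    dot-bracket formats, base-pair precision/recall/F1 evaluation with
    one-position-shift variants and length-weighted aggregation, a seeded
    generator of synthetic stem-loop (optionally pseudoknotted) structures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
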