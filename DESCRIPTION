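Package: gsams
Title: Generalized Suffix Arrays via Compressed Matching Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Suffix sorting for collections of highly similar DNA-like
    sequences (pangenome collections). Computes a compressed representation
    of the matching statistics of every sequence against a reference (the
    CMS and its enhanced variant, the eCMS), uses it to compare arbitrary
    collection suffixes without touching the text, and drives a six-phase
    induced-sorting pipeline that produces the generalized suffix array
    (GSA) of the collection. Includes a self-contained suffix sorter, a
    synthetic-collection generator for mutated reference copies, brute-force
    oracles for validation, FASTA input and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
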