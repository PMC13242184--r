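Package: neffr
Title: Number of Effective Sequences for Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the number of effective sequences (NEFF) of a multiple
    sequence alignment: every sequence is down-weighted by the number of
    sequences (including itself) whose pairwise identity meets a similarity
    threshold, and the weights are summed with an optional length
    normalization. Supports symmetric and asymmetric similarity, query-gap
    and gappy-column preprocessing, protein/DNA/RNA alphabets with
    configurable handling of non-standard residues, per-residue (column-wise)
    NEFF, NEFF for concatenated multimer alignments (homomers and
    heteromers), merging of multiple alignments sharing a query, and
    reading, writing, validation and interconversion of seven alignment
    formats (FASTA, A2M, A3M, Stockholm, ALN, Clustal, PFAM). A
    deterministic synthetic-alignment generator and a command-line interface
    are included.
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
    Biostrings
Config/testthat/edition: 3
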