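Package: sstrscape
Title: Genome-Wide Landscapes of Super-Short Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects maximal super-short tandem repeats (SSTRs; mono- and
    dinucleotide repeat units, total length 2 to 12 bp) in genome sequences,
    bins their densities into fixed-size segments (default 100 kbp), and
    correlates the per-segment densities with G+C content, gene-category
    coverage and retrotransposon count density using the Pearson coefficient.
    Includes the retrotransposon-masking correction used to separate repeat
    content carried inside elements such as SINE Alu from the surrounding
    sequence, a first-order Markov null model that yields z-scores for the
    observed correlations, and a synthetic-genome generator (FASTA, GenBank,
    RepeatMasker and BED outputs) with planted, seed-reproducible structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
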