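Package: mlstkit
Title: Scheme-Driven Multilocus Sequence Typing and Population Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A general toolkit for multilocus sequence typing (MLST) of
    bacterial isolates from per-locus nucleotide sequences. Provides in-silico
    amplicon trimming against scheme primers, allele and sequence-type (ST)
    assignment, per-locus diversity and Nei-Gojobori dN/dS selection
    statistics, index-of-association linkage-disequilibrium (clonality)
    testing with a Monte-Carlo permutation null, eBURST-style clonal-complex
    inference with founder prediction, minimum-spanning trees on allelic
    profiles, UPGMA and neighbour-joining dendrograms, and Bandelt-Dress
    split decomposition for recombination detection. Ships the eight-locus
    scheme for Leuconostoc lactis (carB, groEL, murC, pheS, pyrG, recA,
    rpoB, uvrC) and a synthetic-data generator for clonal and panmictic
    populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
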