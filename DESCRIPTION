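Package: codonlogo
Title: Codon-Level Sequence Logos from Nucleotide Alignments
Version: 0.1.0
Authors@R: person("codonlogo", "developers", role = c("aut", "cre"),
    email = "codonlogo@example.org")
Description: Builds sequence logos of protein-coding nucleotide alignments at
    the codon level rather than per nucleotide. Reads a FASTA alignment whose
    length is a multiple of three, optionally removes duplicate sequences and
    sequences exceeding a chosen fraction of IUPAC-ambiguous nucleotides,
    tabulates codons per position, and converts codon frequencies into
    information content (bits) using Shannon entropy. The position-by-codon
    probability or bit matrix is written as CSV and rendered as a stacked-glyph
    logo (PNG or PDF) with amino-acid-property colour palettes. A seeded
    synthetic-alignment generator supports testing and calibration without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
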