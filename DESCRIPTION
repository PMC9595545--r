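Package: ragfrag
Title: Cryptic RAG Nonamer and CpG Co-Occurrence Analysis at Translocation Breakpoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse chromosomal-translocation fragility driven by
    illegitimate RAG activity. Scans genomes for cryptic recombination signal
    sequence (RSS) nonamers with mismatch tolerance and for CpG dinucleotides,
    tiles the genome into fixed-size windows, classifies break-cluster windows,
    contrasts broken against GC-matched unbroken control windows, measures
    CpG-to-nonamer distance distributions around breakpoints, builds position
    weight matrices of detected nonamers, and stratifies the signal by
    promoter, chromatin class and patient cohort. A synthetic-genome generator
    with planted motifs, CpG-nonamer pairs and a footprint break model
    provides fully ground-truthed inputs for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
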