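Package: circuitseq
Title: Genetic Circuit Characterization from Strand-Specific RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts strand-specific RNA-seq fragment alignments into
    per-nucleotide transcription profiles, corrects the coverage curvature at
    transcript ends using a Monte-Carlo model of the fragment-length
    distribution, and quantifies the performance of genetic parts (promoters,
    terminators, ribozyme insulators) and devices (sensors, NOT/NOR logic
    gates) inside a living circuit via steady-state RNA-polymerase-flux
    models and Hill response-function fitting. Includes tracing of predicted
    transcription profiles from design-tool parameters and a seeded forward
    simulator that generates complete multi-state synthetic experiments for
    end-to-end validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
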