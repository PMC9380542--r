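Package: sosmap
Title: Mapping a Bacterial SOS Regulon from ChIP-Seq, RNA-Seq and SPR Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to map the LexA-controlled DNA-damage (SOS) regulon of a
    bacterium such as Streptomyces venezuelae from first principles: a
    sliding-window local-enrichment peak caller for ChIP-seq coverage with
    control subtraction, strand-aware association of peaks with the promoters
    of transcriptional units, a negative-binomial Wald test for differential
    expression with Benjamini-Hochberg correction, classification of binding
    sites by their dissociation response to DNA damage, ZOOPS
    expectation-maximisation motif discovery and bidirectional PWM scanning
    for the SOS box, and closed-form 1:1 Langmuir modelling plus nonlinear
    least-squares fitting of single-cycle surface plasmon resonance
    sensorgrams. A synthetic-data generator plants SOS boxes, coverage
    tracks, count matrices and sensorgrams with recorded ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    GenomeInfoDb,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
biocViews: ChIPSeq, RNASeq, MotifDiscovery, PeakDetection,
    DifferentialExpression, GeneRegulation, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
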