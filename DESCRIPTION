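Package: imprintr
Title: Co-Transcriptional mRNA Imprinting Analysis from CRAC, Run-On and
    ChIP Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of co-transcriptional RNA binding
    ("imprinting") of a transcription factor and its link to transcription
    kinetics in yeast-scale genomes. Provides polyadenylation-site anchored
    signal matrices and hybrid-scale metagene profiles, k-means
    classification of CRAC binding profiles into CRAC-positive transcripts
    with a per-gene CRAC index, positional scanning for (GCT)n repeat
    motifs, steady-state mRNA half-life estimation from genomic run-on data
    (HL = RA/SR), an RNA polymerase II backtracking index from ChIP versus
    run-on signal, Rpb4/Rpb3 stoichiometry profiles along transcription
    units, hypergeometric gene-set overlap statistics, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
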