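Package: camtakit
Title: Genome-Wide Characterization of the CAMTA Transcription-Factor Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-wide characterization of the
    calmodulin-binding transcription activator (CAMTA) gene family, built
    around the durian (Durio zibethinus) family as the worked case. Covers
    protein physicochemistry in the ProtParam convention (average molecular
    weight, Bjellqvist isoelectric point), domain-architecture annotation
    (hmmscan ingestion plus consensus detection of the calmodulin-binding
    domain, IQ motif and bipartite nuclear localization signal, with
    Eisenberg hydrophobic-moment helical-wheel analysis), exon-intron
    structure and strand-aware promoter extraction from GFF3, paralog
    detection by reciprocal best hit with Nei-Gojobori (1986) Ka/Ks,
    divergence dating and selection classification, neighbor-joining
    phylogenies with bootstrap support, degenerate IUPAC motif scanning of
    promoters with Fisher exact enrichment, TMM-normalized Pearson
    co-expression partner extraction, and relative qPCR quantification by
    the 2^-ddCt method. A seeded synthetic-data generator emulates every
    input with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    edgeR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    seqinr,
    optparse
Config/testthat/edition: 3
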