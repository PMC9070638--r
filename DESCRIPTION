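Package: ncpep
Title: Peptidogenomic Discovery and Genomic Characterization of
    Non-Conventional Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for peptidogenomics: building a six-frame stop-to-stop
    translation database of a genome with exact genomic coordinates, mapping
    mass-spectrometry-identified peptides back to the genome, classifying
    peptides as conventional (in-frame CDS) or non-conventional (intergenic,
    intronic, UTR, upstream/downstream, out-of-frame exonic), summarizing
    their genome-wide distribution (window densities, intensive regions,
    neighbor and TSS distances, chromosome-length correlation, developmental
    stage overlap), overlapping peptide loci with external interval tracks
    (QTLs, LTR retrotransposons, domestication sweeps, lncRNAs, long-read
    alignments), and testing enrichment of peptides in SNP-flanking regions
    against a matched random background. A synthetic-data generator plants
    peptides of known origin into simulated genomes so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
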