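Package: tRFkit
Title: Identification and Quantification of tRNA-Derived Small RNAs from
    Small RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation, conservative read counting, normalization,
    classification and downstream statistics for tRNA-derived non-coding
    RNAs (tRF-5, tRF-3, tsRNA/tRF-1 and 5' leader RNAs) in small RNA-seq
    data. Builds genome-space fragment annotations from tRNA gene
    catalogs (including 20-nt 5' leader loci), counts aligned reads with
    union-overlap semantics while discarding multi-mapping and
    feature-ambiguous reads, normalizes counts to RPM and TPM, filters
    low-expression features by mean log2 TPM, stratifies tRF-5/tRF-3
    into length subclasses, performs moderated-t differential expression
    with empirical-Bayes variance shrinkage and Benjamini-Hochberg FDR,
    and screens expression-covariate correlations. A synthetic-data
    simulator generates genomes, catalogs, reads (FASTQ) and
    truth-aligned BAM files with known fragment abundances so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
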