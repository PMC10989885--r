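Package: duckmeth
Title: Context-Resolved DNA Methylome, Chromatin and Small RNA Analysis for
    Compact Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing analysis in plants
    with reduced RNA-directed DNA methylation, modeled on the duckweed
    (Spirodela polyrhiza) methylome. Provides strand-aware cytosine context
    and subcontext classification (CG/CHG/CHH, CWG/CCG, CWA), symmetric dyad
    pairing, weighted methylation levels at genome, window, and feature
    scale, bisulfite nonconversion estimation from an unmethylated organelle
    contig, per-site and per-gene binomial methylation-enrichment tests with
    Benjamini-Hochberg FDR control and gene-body-methylation (gbM)
    classification, metaplots over gene bodies and flanks, H3K9me2 peak
    occupancy and element-overlap enrichment with an exact Fisher test in
    the bedtools-fisher style, small RNA size-class profiling, and a seeded
    generator of a miniature methylome with known ground truth for
    end-to-end validation.
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
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, Coverage, Sequencing
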