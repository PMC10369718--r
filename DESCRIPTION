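Package: GenomicOverlaps
Title: Parameterized Overlap Association of Genomic Region Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Associates user-supplied genomic regions (genes, differentially
    expressed gene lists, peaks) with annotation region sets such as
    transcription factor binding sites, CpG islands, and promoters.
    Reads BED, GFF3/GTF, and delimited tables into a common 1-based closed
    coordinate model, optionally normalizes chromosome naming, removes
    duplicated intervals, and resizes regions strand-aware around the
    transcription start or termination site. A parameterized overlap engine
    (minimum overlap, overlap type, strand handling) produces annotated hit
    tables, per-query overlap counts with summary statistics, binned
    metagene-style coverage profiles oriented 5' to 3', and static
    visualizations including local genomic track plots and UCSC browser
    links. A synthetic region-set generator with known overlap rates and
    placement biases supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    jsonlite
biocViews: GenomeAnnotation, Coverage, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
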