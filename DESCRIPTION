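Package: dryqc
Title: Degradation-Aware Quality Control for Poly(A)-Selected RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control and degradation-bias analysis for poly(A)-selected,
    single-end RNA-seq experiments that compare a preservation or storage
    treatment against matched controls. Provides per-sample library metrics
    (unique mapping, duplication, GC, chromosome and biotype distributions),
    per-cycle mismatch profiling with group comparison at controlled FDR,
    gene-body coverage over 40 meta-transcript bins, cumulative gene
    diversity curves, gene-level FPKM quantification with expression and
    biotype filters, a 40-bin read-count-ratio regression that classifies
    genes as uniformly downsampled or 5'/3'-end underrepresented,
    transcript-feature and AU-rich-element enrichment of gene sets, and
    efficiency-corrected RT-qPCR integrity ratios. A molecule-level
    simulator of degraded poly(A)-selected libraries (fragmentation-driven
    5' loss, uniform decay, PCR duplication, positional mismatch errors)
    generates SAM alignments with ground truth so every stage can be
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
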