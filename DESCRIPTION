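Package: excapr
Title: Transcriptome-Based Exon Capture Design, Evaluation and SNP Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-genome-free toolkit for hybridization exon capture in
    non-model organisms. Designs tiling capture probes (60-bp oligos, class-specific
    tiling steps, 1-bp edge densification) from de novo transcriptome assemblies with
    15-mer soft-masking of repetitive probes; filters multiplexed capture reads
    (demultiplexing by 7-nt barcodes, exact-duplicate removal, adapter and quality
    trimming, low-complexity and contaminant screening); merges redundant assemblies
    and identifies in-target contigs by reciprocal best hit; computes capture
    performance metrics (sensitivity, specificity, coverage uniformity, edge effects,
    GC dependence, reproducibility, divergence decay); estimates empirical sequencing
    error from haploid loci (mitochondrial, X-linked in males, SRY); and calls and
    classifies SNPs (fixed versus polymorphic; synonymous, non-synonymous, intron,
    UTR) across species. A built-in capture-experiment simulator generates
    ground-truth gene spaces, diverged species, and reads, so every stage is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
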