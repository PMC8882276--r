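Package: alemut
Title: Mutation Analysis for Adaptively Evolved Diploid Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parent-versus-evolved genome analysis for diploid strains from
    adaptive laboratory evolution experiments. Classifies every genotype
    difference between an evolved isolate and its parent as a de novo variant
    or a loss-of-heterozygosity (LOH) event with zygosity and
    reversion-to-reference subtyping, annotates coding-sequence effects
    (missense, nonsense, frameshift with altered-tail accounting), clusters
    LOH calls into chromosomal segments shared across lineages, estimates
    copy number from median-normalized read depth with per-gene and
    chromosome-level calls, and produces cohort-level mutation accounting
    tables. Includes a synthetic diploid-evolution generator with
    machine-readable ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
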