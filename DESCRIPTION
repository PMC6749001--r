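Package: lineageSV
Title: Lineage-Specific Structural Variant Inference on Synthetic Catarrhine Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative-genomic analysis of great-ape and Old World
    monkey assemblies at desk scale: assembly gap finding and flank-anchored gap
    closure, quality-value (QV) scoring and contiguity statistics, a minimal
    unique-k-mer anchor and colinear-chaining engine for pairwise structural
    variant (SV) calling between assemblies, reciprocal-overlap SV set algebra,
    ape-specific SV (ASSV) inference by forward/reverse concordance, cross-ape
    intersection and outgroup polarization, ape-monkey differential enhancer
    (ADE) calling from H3K27Ac count matrices, and permutation-based trait
    gene-set enrichment. A seeded simulator generates catarrhine genomes with
    SVs planted on labelled phylogeny branches, N-gapped references, enhancer
    count matrices and SV genotype tables, so the whole pipeline is exercised
    end-to-end against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
biocViews: StructuralVariation, Alignment, Coverage, Sequencing, Software
RoxygenNote: 7.3.3
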