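Package: shorthap
Title: Genome-Wide Molecular Fingerprinting with Read-Backed Short Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based molecular fingerprinting of diploid cohorts from
    whole-genome shotgun alignments. Defines fixed-width sliding-frame loci over
    a reference assembly, phases neighbouring SNPs into multi-allelic short
    haplotypes using read-backed phasing within each frame, converts haplotype
    read frequencies into discrete diploid dosage calls, and filters loci on
    call completeness and dosage correctness. Downstream estimators include
    Nei-Chesser observed/expected heterozygosity and inbreeding coefficients,
    windowed nucleotide diversity, pairwise Nei FST, genotype PCA, pairwise
    Jaccard Inverse Distance relatedness with locus bootstrap, and
    Neighbor-Joining trees with bipartition support. A hierarchical
    two-species population simulator (reference, phased cohort, aligned reads,
    truth VCF) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
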