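Package: ldrefine
Title: Linkage-Disequilibrium Draft-Genome Refinement and Rearrangement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines fragmented draft genome assemblies using linkage
    disequilibrium (LD) measured in population resequencing data: r2 linkage
    scores between scaffold-end SNP windows are aggregated into a terminal
    score matrix, scaffolds are ordered and oriented by solving a weighted
    graph over scaffold terminals, cycles are linearized at a threshold
    derived from a Gaussian null fit to the score distribution, and the
    resulting super-scaffolds are emitted as FASTA plus AGP with native
    assembly statistics (N50/N90 and length-class counts). A second stage
    consumes whole-genome alignment coordinate tables, filters and intersects
    homologous blocks across genomes, and classifies inversions and
    translocations from signed block permutations, including a majority-rule
    reconstruction of ancestral block adjacencies for a three-genome topology.
    A synthetic-data module simulates chromosomes, fragmented scaffold sets,
    founder-mosaic population genotypes with distance-decaying LD, and
    alignment tables with planted rearrangements, so every stage is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
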