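Package: binmapqtl
Title: Superdense Bin Maps and Seed-Coat-Color QTL Analysis for F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds superdense genetic bin maps from low-coverage
    resequencing genotypes of F2 intercross populations and maps
    quantitative trait loci for seed coat color. Implements A/H/B genotype
    coding from joint-called variants, redundant-marker collapsing,
    sliding-window genotype error correction, bin construction,
    segregation-distortion filtering, EM estimation of pairwise
    recombination fractions, LOD-based linkage grouping, Kosambi map
    distances, Haley-Knott interval mapping and composite interval mapping
    with permutation significance thresholds, consolidation of QTL
    intervals into physical segments, and screening of candidate genes by
    co-segregating high-impact variants combined with stage-wise
    differential expression. Includes a synthetic-cross simulator so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    MASS,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
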