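Package: diffqtl
Title: Concordance Between Breed Differentiation Scans and Line-Cross QTL
    Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing genome scans of between-population genetic
    differentiation with linkage-mapping evidence for quantitative trait
    loci (QTL) obtained from an experimental cross of the same populations.
    Implements per-locus allele-frequency differences (delta) and pairwise
    Weir-Cockerham F_ST with sample-size adjustment, 100-kb binning and
    moving-average smoothing of differentiation tracks, Haley-Knott
    line-cross regression interval mapping (additive + dominance) on a
    100-kb grid with permutation significance thresholds, and
    concordance analyses: per-chromosome and genome-wide correlations,
    threshold-grouped means with one-tailed exact Wilcoxon signed-rank
    tests, top-percentile region extraction, and discovery-panel subset
    reanalysis. A synthetic-data generator (Balding-Nichols breed
    divergence plus a three-generation F2/backcross pedigree simulated
    under Haldane recombination) makes the full pipeline testable without
    external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
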