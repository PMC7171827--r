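Package: sweepscan
Title: Selective-Sweep Scans and Population Structure from SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed genome scans for selective sweeps from multi-sample
    SNP genotype data: Weir-Cockerham fixation index (FST) in sliding
    windows, locus-specific branch length (LSBL) for a focal population
    against a contrast population and an outgroup, windowed nucleotide
    diversity (pi) and pi-ratio, empirical top-percentile outlier calling
    and window-to-gene annotation with two-test overlap.  Supporting
    stages cover variant summaries (Ts/Tv, per-sample genotype counts),
    LD pruning, genotype PCA, identity-by-state distances with
    neighbor-joining trees and site-bootstrap support, and region
    haplotype matrices for reference/alternative heatmaps.  A
    three-population Balding-Nichols simulator with injected focal-branch
    sweeps provides fully specified synthetic datasets with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    graphics,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
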