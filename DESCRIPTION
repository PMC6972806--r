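Package: bloomsweep
Title: Selective-Sweep Scans and Blooming-Time Association for Resequenced Plant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic scans for selective sweeps between
    phenotype groups of a resequenced diploid panel, built for blooming-time
    contrasts in Prunus mume but applicable to any small multi-sample VCF.
    Computes per-individual diversity summaries (observed heterozygosity,
    per-individual pi, F_IS), sliding-window nucleotide diversity, Watterson's
    theta and Weir-Cockerham F_ST, a log2 pi-ratio between groups, joint
    empirical-tail outlier regions with gene overlap and 1-Mb segmentation
    rules, linkage-disequilibrium decay curves, and a kinship-corrected
    (EMMAX-style) mixed-model association stage with Benjamini-Hochberg
    correction. Includes a Balding-Nichols genotype simulator that emits
    VCF/GFF3 fixtures with planted sweeps and causal variants so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
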