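Package: centrodrive
Title: Population Genomics and Quantitative Genetics of Centromere-Associated Meiotic Drive
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and dates selective sweeps associated with a driving
    centromeric haplotype from inbred resequencing panels, and maps unlinked
    modifiers of female meiotic drive from intercross progeny data. Provides
    missing-data-aware per-gene diversity statistics (nucleotide diversity,
    Tajima's D, between-class divergence, gene-pair linkage disequilibrium),
    sweep dating by mutation accumulation (Thomson TMRCA estimator) and by
    haplotype-length decay around a focal gene, a forward Wright-Fisher
    simulator of mutation accumulation on a non-recombining haplotype,
    contiguous-gene-block permutation outlier tests, read-depth copy-number
    classification, transmission-ratio phenotyping of selfed progeny, and a
    regression-on-genotype-probability LOD scan with a binary drive-locus
    cofactor. Synthetic-data generators with known truth make every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    withr,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
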