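Package: sweepscan
Title: Selective Sweep Detection from Pooled Heterozygosity and Windowed FST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scan for signatures of artificial selection in a focal
    population contrasted against a wild reference population. Computes pooled
    heterozygosity (Hp) from major/minor allele counts and a nucleotide-diversity
    based fixation index (FST) in sliding genomic windows (100 kb, 10-kb step by
    default), Z-transforms both statistics genome-wide, calls jointly extreme
    windows at empirical quantile thresholds, merges them into candidate sweep
    regions and intersects them with a gene annotation. Includes the SNP quality
    filters typically applied after population-scale variant calling (mapping
    quality, depth, adjacent-SNP spacing, per-pool missingness) and a
    Balding-Nichols two-population simulator with planted sweeps that emits
    VCF, population map, GFF3 and truth files so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
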