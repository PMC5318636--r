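Package: varscape
Title: Variant Landscape Analysis for Resequenced Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for characterising the genome-wide
    polymorphism landscape of resequenced genomes against a reference, as is
    done in crop resequencing studies of rice landraces. Reads per-sample
    variant calls (VCF), applies VarScan-style qualification thresholds, bins
    variants into fixed non-overlapping windows (100 kb by default), detects
    SNP deserts (maximal runs of windows below 1 SNP/kb), computes the base
    change spectrum and transition/transversion ratio, annotates variant
    consequences natively against GFF3 gene models (intergenic, regulatory
    flanks, intron, UTR, synonymous/nonsynonymous CDS), flags outlier genes
    by the Tukey box-and-whisker upper fence on per-gene nonsynonymous SNP
    density, and clusters samples by Pearson correlation of windowed SNP
    densities. Includes a fully deterministic synthetic-data generator
    (reference FASTA, GFF3 gene models, multi-sample VCFs with ground truth)
    emulating a two-subspecies design for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
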