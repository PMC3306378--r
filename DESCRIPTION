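Package: pantx
Title: Pan-Transcriptome Diversity Analysis from Multi-Line RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequence and expression diversity across a
    panel of homozygous inbred lines profiled by RNA-seq. Implements a
    multi-sample SNP caller operating on per-base read-count pileups with
    allele-frequency and read-support thresholds, genotyping-by-sequencing
    (GBS) barcode demultiplexing and majority-rule genotype calling,
    cross-method genotype concordance, Rogers genetic distances with
    neighbor-joining tree construction, classification of gene expression
    from FPKM confidence intervals into core and dispensable transcriptomes,
    and presence/absence classification of de novo assembled transcripts
    with heterotic-group-specific set analysis. A seeded simulator generates
    complete miniature study panels (genotype truth, pileups, FPKM tables,
    alignment summaries, read support) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
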