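Package: rspofind
Title: Stroma-Corrected Outlier Expression, Fusion-Transcript Detection,
    and Paired Variant Discovery for RSPO-Rearranged Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nominates colorectal tumor samples likely to carry RSPO3
    gene fusions from bulk expression data by correcting outlier
    expression for stromal content (delta Z-score on target expression
    minus a cancer-associated-fibroblast score), detects fusion
    transcripts from RNA-seq reads with a self-contained k-mer
    seed-and-extend split-read aligner with anchor-length calling
    criteria and exon/reading-frame annotation, and discovers variants
    that discriminate a drug-resistant derivative from its parental
    cell population by per-site Fisher exact testing of allele counts
    with frameshift and biallelic loss-of-function annotation. Ships
    synthetic-data generators that emulate each input (stromally
    confounded expression cohorts, junction-spanning reads on toy gene
    models, paired deep pileups with planted variants) with full
    ground-truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
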