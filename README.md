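# rspofind

Stroma-corrected outlier expression analysis, split-read fusion-transcript
detection, and paired parental-vs-resistant variant discovery — the
computational workflow for finding RSPO3-fusion-positive colorectal
cancer samples and explaining acquired resistance to WNT-pathway
blockade, implemented as a tested R package with synthetic-data
generators for every input.

## Who this is for

Bulk RSPO3 expression is a poor fusion screen on its own: in an
unrearranged colorectal tumour, RSPO3 mRNA comes almost entirely from
stromal cells, so stroma-rich samples look like overexpressors. This
package is for computational biologists who want the stroma-corrected
version of that screen — and the downstream read-level and variant-level
confirmations — as reusable, testable functions rather than a one-off
analysis script.

## The statistics at the core

* **Delta outlier statistic.** Per sample, the CAF score is the mean
  log2 expression of a cancer-associated-fibroblast signature;
  `delta = expr(target) − CAF score`. Samples with expression Z-score
  > 2 are screening candidates; samples with delta Z-score > 2.5 (Z
  computed cohort-wide, sample sd) are fusion candidates, and
  candidates are partitioned by the sign of delta. A saturation search
  ranks the remaining samples by expression stratum and ascending CAF
  score within stratum.
* **Split-read fusion calling.** A transcriptome k-mer (k = 21)
  seed-and-extend aligner classifies each read as linear, split or
  unaligned; a split requires ≥ 25 mapped nucleotides on each end of
  the read and two different genes. Splits are clustered by exact
  breakpoint pair into calls with supporting-read counts, exon-boundary
  annotation and reading-frame status (in-frame iff retained 5' CDS
  length ≡ discarded 3' CDS offset mod 3).
* **Paired Fisher discordance.** Per aligned site, a two-sided Fisher
  exact test (minimum-likelihood rule, log-space hypergeometric) on the
  ref/alt × sample table; calls require resistant allele frequency
  ≥ 1.5%, p ≤ 0.05, allele gain, and depth ≥ 20. Frameshift indels and
  protein effects (`p.G265fs` style) are annotated, and two distinct
  heterozygous truncating calls in one gene flag biallelic
  (functionally homozygous) loss of function.

## Worked example

```r
library(rspofind)

# 450-sample cohort, 6 planted fusion-positive samples, fixed seed
sim    <- simulate_cohort_expression(cohort_sim_config(seed = 7))
scores <- compute_stromal_scores(sim$expr, sim$signatures)
report <- delta_outlier_analysis(sim$expr, "RSPO3", scores,
                                 z_expr = 2, z_delta = 2.5)

truth <- sim$truth$samples
pearson(sim$expr["RSPO3", !truth$fusion_status],
        scores$caf[!truth$fusion_status])
#> [1] 0.9453058
sum(report$delta_outlier[truth$fusion_status[match(report$sample, truth$sample)]])
#> [1] 6
cands <- select_expression_outliers(report)
partition_by_delta_sign(report, cands)$positive
#> [1] "S130" "S273" "S005" "S119" "S446" "S413"
```

The correlation (0.95) is the stromal confounding the delta statistic
removes; all 6 planted fusion-positive samples exceed delta Z 2.5 and
land exclusively in the positive-delta group of the candidates.

```r
toy <- make_toy_gene_models(seed = 3)
idx <- build_reference_index(toy$models, toy$genome)
rd  <- simulate_fusion_reads(
  fusion_sim_spec(breakpoint5 = 13, breakpoint3 = 2,
                  anchor_length_list = rep(c(28, 35, 42), 4), seed = 5),
  toy$models, toy$genome)
call_fusions(align_reads(rd$reads, idx), toy$models)
#>    gene5 exon5 breakpoint5  gene3 exon3 breakpoint3 support    frame         boundary
#> 1 PTPRKL    13        2046 RSPO3L     2         103      12 in-frame at-exon-boundary
```

Twelve junction reads with anchors ≥ 25 yield one exon-13 → exon-2
in-frame call with support 12; planted 24-base anchors are never
reported (the anchor rule is sharp).

```r
fx    <- axin_resistance_fixture(seed = 42)
calls <- call_discordant_variants(fx$parental, fx$resistant)
calls$protein_effect <- vapply(seq_len(nrow(calls)), function(i)
  annotate_protein_effect(calls[i, ], fx$model, fx$genome), character(1))
calls[, c("pos", "af_resistant", "class", "support", "protein_effect")]
#>    pos af_resistant    class support protein_effect
#> 1  892    0.4516129 deletion      28       p.G265fs
#> 2 2602    0.5238095 deletion      88       p.V835fs
infer_biallelic_loss(calls, "AXIN1L")$biallelic
#> [1] TRUE
```

Two resistant-specific single-base deletions, both frameshift and both
heterozygous: a functionally homozygous loss of the WNT-inhibitor gene.

A command-line wrapper over the same functions ships in
`inst/cli/rspofind` (`rspofind {simulate,score,fuse,variants,run}`), and
`run_pipeline()` executes the full synthetic demonstration with a JSON
run log (seed, thresholds, artifact checksums).

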