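---
title: "Stroma-corrected outlier expression, split-read fusion detection, and paired variant discovery"
author: "rspofind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroma-corrected outlier expression, split-read fusion detection, and paired variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspofind)
```

## The problem

RSPO3 gene fusions (canonically PTPRK–RSPO3) activate WNT signalling in a
small fraction of colorectal cancers and are therapeutically actionable,
but naive screens for high RSPO3 expression in bulk tumour profiles are
confounded: in an unrearranged tumour, essentially all RSPO3 mRNA comes
from stromal cells, not from the epithelial cancer cells. A sample can
therefore express RSPO3 highly simply because it is stroma-rich. The
pipeline in this package addresses three linked tasks:

1. **Nominate fusion candidates from expression.** Score each sample's
   stromal content with a cancer-associated-fibroblast (CAF) expression
   signature, subtract the CAF score from the target-gene log2
   expression (the *delta* statistic), and flag samples whose delta
   Z-score is extreme — expression that stroma cannot explain.
2. **Confirm fusions from reads.** A self-contained split-read caller
   finds junction-spanning RNA-seq reads whose two segments map to two
   different genes, each with at least 25 mapped nucleotides on its end
   of the read, then annotates exon boundaries and reading frame.
3. **Explain acquired resistance.** Compare deep allele counts between
   a parental and a drug-resistant cell population site by site with a
   two-sided Fisher exact test, keep variants gained in the resistant
   population at ≥ 1.5% allele frequency and 5% significance, classify
   frameshifts, and recognise compound-heterozygous (functionally
   homozygous) loss of a gene such as AXIN1.

Real cohorts of this design (a 450-sample TCGA colorectal RNA-seq
compendium, exomes of paired cell populations) are too large to ship, so
every input is emulated by a generator with a complete ground-truth
record; all quantitative claims in the test suite are made against that
truth.

## The cohort generative model

For sample $i$ let $f_i \in [0,1]$ be its stromal fraction, drawn
Beta$(2,2)$. Each signature gene $g$ (CAF, endothelial or leukocyte
class) has a fixed linear-scale coefficient $S_g$, drawn log-uniformly
on $[100, 2000]$, and observed expression

$$x_{gi} = \log_2\!\left(1 + S_g f_i\right) + \varepsilon_{gi},
  \qquad \varepsilon_{gi} \sim N(0, \sigma^2),$$

with $\sigma = 0.3$ log2 units by default. The target gene adds an
epithelial component present only in fusion-positive samples:

$$x_{ti} = \log_2\!\left(1 + S_t f_i + E\,[\text{fused}_i]\right)
  + \varepsilon_{ti},$$

with $S_t = 500$ (mid-range of the signature coefficients) and
$E = 1500$ — an overexpression comparable to the strongest stromal
signal, which is what a strong constitutive promoter fused upstream of
the gene produces. Background genes are independent of $f_i$. Planted
fused samples draw $f_i$ from the lower tertile of the Beta
distribution, reflecting that fusion carriers in the motivating data
were low-stroma samples; the range is configurable so the confounded
(high-stroma fused) regime can also be exercised. Defaults are 450
samples, 30 genes per signature, 100 background genes and 6 fused
samples, mirroring the scale of the motivating TCGA analysis.

Two properties of this model matter for interpretation:

* Because all three stromal classes scale with the same $f_i$, the
  CAF/Endo/Leuco scores are strongly correlated, as they are in real
  bulk tumours; only the CAF score enters the default delta statistic,
  the others are reported (and can be substituted via
  `score_column`).
* The log2 observation of a linear-scale mixture is curved, so even
  with $\sigma = 0$ the *linear* (Pearson) correlation between target
  expression and stromal fraction saturates near 0.95 rather than 1;
  tests assert $r > 0.9$ noise-free and $r \ge 0.7$ under default
  noise.

What the generator does **not** emulate: gene–gene correlation beyond
the shared stromal factor, count-level (negative binomial) noise,
batch or platform effects, and tumour subtype structure. Passing tests
therefore demonstrate that the statistics behave as designed when their
assumptions hold — not that the thresholds (Z > 2, delta Z > 2.5) are
optimal for any particular real cohort.

## The delta outlier statistic

For target gene $t$, sample $i$:
$\delta_i = x_{ti} - \mathrm{CAF}_i$, computed on raw log2 values —
the subtraction is taken literally rather than on per-feature Z-scores
(a Z-minus-Z variant can be obtained by standardising upstream; it was
deliberately not made the default because the raw difference keeps
log-fold-change units). Both $x_{t\cdot}$ and $\delta$ are standardised
cohort-wide with the sample ($n-1$) standard deviation; with $n = 450$
the choice of denominator is immaterial, and $n-1$ matches standard
statistical software. A zero-variance vector standardises to all zeros
with a `degenerate` flag rather than NaN.

Samples with target Z above `z_expr = 2` are *expression outliers* (the
screening set); samples with delta Z above `z_delta = 2.5` are
*stroma-corrected outliers* (the fusion candidates). Candidates are
partitioned by the sign of $\delta$; a delta of exactly 0 goes to the
negative group, since candidacy requires strictly positive
stroma-unexplained expression. No multiple-testing correction is
applied anywhere in this module: the thresholds act as fixed
effect-size cutoffs, not as hypothesis tests.

The *saturation search* formalises "for any expression level, take the
samples with the lowest stromal content": eligible samples (not already
expression outliers, not excluded) are ranked by descending
target-expression stratum and ascending CAF score within stratum.
"Expression level" is made operational as deciles of the cohort target
expression computed from quantile breaks, so tied expression values
always share a stratum.

## The split-read aligner

The established fusion callers the field uses (deFuse, ChimeraScan,
MapSplice, BWA+BLAT hybrids) are genome-scale tools; here the calling
criteria themselves are the object of study, so the aligner is a small,
fully specified transcriptome seed-and-extend:

* **Index**: exact k-mers (k = 21) over the spliced transcript
  sequences. K-mers shared by two genes are marked ambiguous and never
  seed; a read seedable only by ambiguous k-mers stays unaligned.
* **Seeding**: every k-mer of the read (both orientations) is looked
  up; each hit defines a (gene, diagonal) candidate.
* **Extension**: along each diagonal the read is compared exactly. A
  *linear* placement covers the whole read with at most
  `max_mismatch = 2` substitutions. A *split* pairs a prefix segment
  and a suffix segment from two different genes, each with at least
  `min_anchor = 25` bases on its end of the read and at most
  `max_mismatch` substitutions, tiling the read within `slack = 0`
  bases. "Mapped nucleotides" counts the segment span (internal
  mismatches included), but each segment must *end on a matching base
  at the junction side* — without that trimming rule, a true 24-base
  anchor could annex cross-gene mismatches and defeat the 25-base
  threshold, which the tests require to be sharp (24 never reported,
  25 always).
* **Tie-breaking** is deterministic: maximal matched bases, then fewer
  mismatches, then lexicographic gene pair, then smallest junction
  offset. A linear placement beats a split of equal score.

Splits are clustered by exact breakpoint pair (simulated and
splice-derived junctions are base-precise; a ±2 merge window is
available via `slack`), with cluster size as supporting-read count and
`min_support = 2` by default (single-read fusion calls are noise-prone;
set 1 to reproduce maximal sensitivity). A junction is in-frame when
the 5'-retained CDS length and the 3'-discarded CDS offset are
congruent modulo 3. Exon coverage of the 3' gene provides the
exon-1-absence check: a gene expressed exclusively through a fusion
transcript has no reads on its first exon.

Two limitations are inherent to the stated algorithm and are therefore
documented rather than patched: a substitution that falls inside every
k-window of a short anchor defeats seeding (so recovery guarantees are
asserted at zero error rate, plus interior-error cases); and genome-
space events (intronic breakpoints, unannotated splice forms) are out
of scope — the index is transcriptomic.

The toy genome used in tests makes these guarantees checkable by
construction: the 14-exon 5' gene uses only the letters A/C and the
4-exon 3' gene only G/T, so the two transcripts share no k-mer of any
length; all exon lengths are multiples of 3, so both the exon-1 and
exon-13 junctions into the 3' gene's exon 2 are in-frame.

## Paired variant discovery

Inputs are per-site allele-count tables for a parental and a resistant
population (the alignment, duplicate-marking and pileup steps that
produce such tables in a real pipeline are deliberately outside this
package's scope; for raw reads the package provides only Phred-based
masking, which replaces bases under quality 20 with `N` rather than
excising them, preserving pileup coordinates). A site is called when:

1. both samples have depth ≥ 20 (a floor added to avoid degenerate
   frequency estimates at shallow sites),
2. the resistant-sample allele frequency is ≥ 1.5%,
3. the allele is *gained*: AF resistant > AF parental, and
4. the two-sided Fisher exact p-value of the ref/alt × sample table is
   ≤ 0.05.

The Fisher test uses the minimum-likelihood two-sided rule (the common
convention, also used by `stats::fisher.test`), summing hypergeometric
terms no more likely than the observed table within relative tolerance
1e-7, evaluated in log space. The implementation is validated against a
binomial-coefficient enumeration oracle over every 2×2 table with
margins up to 30 (about 164,000 tables, agreement within 1e-9) and is
conservative under the null: on 10,000 simulated equal-frequency sites
at depth 100, fewer than 6% reach p ≤ 0.05. No multiple-testing
correction is applied by default, matching the uncorrected 5% level of
the original design; Benjamini–Hochberg is available via
`adjust = "BH"`.

Indels are classified by allele-length difference, frameshift when not
a multiple of 3. Protein effects use the standard genetic code on the
gene model's CDS: `p.G265fs`-style strings for frameshifts, `del`/`ins`
for in-frame events, `p.K3*` for stop gains. Biallelic
(functionally homozygous) loss is inferred when at least two distinct
truncating calls each lie in the heterozygous allele-frequency band
[0.3, 0.7] — phasing being unknown, two independent heterozygous hits
are interpreted as striking both alleles, and the summary string states
that assumption. The band is a package choice; the motivating
observation reports only that both events were heterozygous.

The packaged resistance fixture plants two single-base deletions in the
coding sequence of a toy 840-codon WNT-inhibitor-like gene (codons 265
and 835, engineered to encode glycine and valine) at heterozygous
frequency in the resistant sample only, with mean depths 66 and 180 so
the expected supporting-read counts are 33 and 90. The fixture's
low-frequency companion case plants a variant at 1% frequency *in both
populations* (subclonal drift shared by parental and resistant cells,
as expected in a microsatellite-instable background): such variants are
excluded by the allele-frequency floor, and across 100 seeded
replicates none is called, while the heterozygous resistant-specific
variant at depth 200 is called in all 100.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GTF/VCF/pileup files
  are 1-based inclusive, converted only at I/O boundaries.
* Every generator is a pure function of (config, seed); child RNG
  streams are derived per component so adding a component does not
  reshuffle the others.
* A Fisher p summing to 1 within 1e-12 is clamped to exactly 1, so a
  proportion-identical table reports p = 1.
* `cut`-based strata use quantile breaks (ties share strata);
  delta = 0 is assigned to the negative group; degenerate standard
  deviations yield flagged zeros, never NaN.
* Problem sizes in tests: the 450-sample default cohort, 12-read
  fusion simulations with up to 1,000 background reads, the
  margins-≤-30 Fisher sweep, a 10,000-site null pileup and 100-replicate
  operating-characteristic runs — all chosen so the full suite
  completes in well under a minute while still exercising cohort-scale
  behaviour.

## Known limitations

* The aligner is transcriptome-only, substitution-only (no indels in
  reads), single-end, and exact-breakpoint; it is a vehicle for the
  calling criteria, not a replacement for a production fusion caller.
* The delta statistic presumes the stromal signature is valid for the
  tissue; signature genes missing from a matrix are reported but a
  systematically biased signature cannot be detected internally.
* The variant module consumes aligned counts; it cannot model
  alignment artefacts (strand bias, indel realignment) and its Fisher
  test treats reads as independent draws.
* Synthetic cohorts omit batch effects and count-level noise; the
  reported operating characteristics are properties of the model, not
  of any real dataset.
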