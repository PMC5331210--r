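#' Hard-mask low-quality bases
#'
#' Bases with Phred quality strictly below `threshold` are replaced by
#' `N` so they are excluded from downstream allele counting while
#' preserving read coordinates (physical excision would shift every
#' pileup position).
#'
#' @param sequence Read sequence.
#' @param quality Phred+33 quality string of equal length.
#' @param threshold Minimum Phred quality retained (default 20).
#' @return Masked sequence with an integer `n_masked` attribute.
#' @export
mask_low_quality <- function(sequence, quality, threshold = 20) {
  if (nchar(sequence) != nchar(quality))
    stop("sequence and quality have different lengths")
  q <- char_to_phred(quality)
  ch <- strsplit(sequence, "")[[1]]
  low <- q < threshold
  ch[low] <- "N"
  out <- paste(ch, collapse = "")
  attr(out, "n_masked") <- sum(low)
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value for the table `rbind(c(a, b), c(c, d))` by the
#' minimum-likelihood rule: with margins fixed, the probabilities of all
#' tables no more likely than the observed one (within relative
#' tolerance 1e-7) are summed. Hypergeometric terms are evaluated in
#' log space for numerical stability.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 + m2 == 0) stop("empty table")
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  logp <- dhyper(x, m1, m2, k, log = TRUE)
  obs <- logp[x == a]
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  # when every table is included the sum is 1 up to rounding; clamp so a
  # proportion-identical table reports exactly 1
  if (p >= 1 - 1e-12) 1 else p
}

#' Classify an allele pair as SNV, insertion or deletion
#'
#' Alleles are VCF-style (anchored): equal lengths give an SNV,
#' otherwise the class follows the longer allele and the event length is
#' the length difference. Frameshift when the indel length is not a
#' multiple of 3.
#'
#' @param ref,alt Allele strings.
#' @return List with `class` (`"SNV"`, `"insertion"`, `"deletion"`),
#'   `length` (0 for SNV) and logical `frameshift`.
#' @export
classify_indel <- function(ref, alt) {
  if (nchar(ref) == 0 || nchar(alt) == 0) stop("empty allele string")
  dl <- nchar(alt) - nchar(ref)
  if (dl == 0)
    return(list(class = "SNV", length = 0L, frameshift = FALSE))
  list(class = if (dl > 0) "insertion" else "deletion",
       length = abs(dl), frameshift = abs(dl) %% 3 != 0)
}

#' Call variants discordant between a parental and a resistant sample
#'
#' Site-by-site comparison of two aligned allele-count tables. A site is
#' called when the resistant-sample allele frequency is at least
#' `min_af`, the two-sided Fisher exact p-value of the ref/alt-by-sample
#' 2x2 table is at most `alpha`, and the alt allele is gained in the
#' resistant sample (`AF_resistant > AF_parental`). Sites below
#' `min_depth` in either sample are not tested. No multiple-testing
#' correction is applied by default; `adjust = "BH"` switches the alpha
#' cut to Benjamini-Hochberg-adjusted p-values.
#'
#' @param parental,resistant Site-count data.frames (`contig`, `pos`,
#'   `ref`, `alt`, `ref_count`, `alt_count`) over the same sites.
#' @param min_af Minimum resistant-sample allele frequency
#'   (default 0.015, i.e. 1.5 percent).
#' @param alpha Fisher significance level (default 0.05).
#' @param min_depth Minimum depth per sample at tested sites.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of calls: site and alleles, per-sample counts and
#'   frequencies, `fisher_p`, `class`, `indel_length`, `frameshift`, and
#'   `support` (resistant alt count).
#' @export
call_discordant_variants <- function(parental, resistant, min_af = 0.015,
                                     alpha = 0.05, min_depth = 20,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  key_p <- paste(parental$contig, parental$pos, parental$ref, parental$alt)
  key_r <- paste(resistant$contig, resistant$pos, resistant$ref, resistant$alt)
  if (!identical(sort(key_p), sort(key_r)))
    stop("parental and resistant tables cover different sites")
  resistant <- resistant[match(key_p, key_r), ]
  depth_p <- parental$ref_count + parental$alt_count
  depth_r <- resistant$ref_count + resistant$alt_count
  testable <- depth_p >= min_depth & depth_r >= min_depth
  p <- parental[testable, ]; r <- resistant[testable, ]
  af_p <- p$alt_count / (p$ref_count + p$alt_count)
  af_r <- r$alt_count / (r$ref_count + r$alt_count)
  pre <- af_r >= min_af & af_r > af_p
  fisher_p <- rep(NA_real_, nrow(p))
  fisher_p[pre] <- vapply(which(pre), function(i)
    fisher_exact_2x2(p$ref_count[i], p$alt_count[i],
                     r$ref_count[i], r$alt_count[i]), numeric(1))
  pcut <- fisher_p
  if (adjust == "BH")
    pcut[pre] <- stats::p.adjust(fisher_p[pre], method = "BH")
  called <- pre & !is.na(pcut) & pcut <= alpha
  idx <- which(called)
  cls <- lapply(idx, function(i) classify_indel(p$ref[i], p$alt[i]))
  out <- data.frame(
    contig = p$contig[idx], pos = p$pos[idx], ref = p$ref[idx],
    alt = p$alt[idx],
    ref_count_parental = p$ref_count[idx], alt_count_parental = p$alt_count[idx],
    ref_count_resistant = r$ref_count[idx], alt_count_resistant = r$alt_count[idx],
    af_parental = af_p[idx], af_resistant = af_r[idx],
    fisher_p = fisher_p[idx],
    class = vapply(cls, `[[`, character(1), "class"),
    indel_length = vapply(cls, `[[`, integer(1), "length"),
    frameshift = vapply(cls, `[[`, logical(1), "frameshift"),
    support = r$alt_count[idx],
    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) "X" else aa
}

#' HGVS-like protein-effect annotation
#'
#' Maps a variant onto the CDS of a gene model and reports a compact
#' protein-level string: `p.{AA}{codon}fs` for frameshift indels,
#' `p.{AA}{codon}del` for in-frame deletions, `p.{AA}{codon}{AA'}` for
#' missense SNVs (`p.{AA}{codon}=` when synonymous, `p.{AA}{codon}*`
#' for stop gains). The codon index is `floor(cds_offset / 3) + 1` of
#' the first changed base; the reference amino acid comes from the
#' standard genetic code. Variants outside the CDS annotate as
#' `"non-coding"`.
#'
#' @param variant List or one-row data.frame with `pos`, `ref`, `alt`
#'   (VCF-style; for indels the first changed base is `pos + 1`).
#' @param model A [gene_model()] with CDS.
#' @param genome Named character vector of contig sequences.
#' @return Annotation string.
#' @export
annotate_protein_effect <- function(variant, model, genome) {
  ref <- as.character(variant$ref); alt <- as.character(variant$alt)
  pos <- as.numeric(variant$pos)
  cls <- classify_indel(ref, alt)
  # first changed base: the anchored base for SNVs, the base after the
  # anchor for indels
  changed_pos <- if (cls$class == "SNV") pos else pos + 1
  off <- cds_offset(model, changed_pos)
  if (is.na(off)) return("non-coding")
  codon_idx <- floor(off / 3) + 1
  cds <- cds_sequence(model, genome)
  codon <- substr(cds, 3 * (codon_idx - 1) + 1, 3 * codon_idx)
  aa <- translate_codon(codon)
  if (cls$frameshift)
    return(sprintf("p.%s%dfs", aa, codon_idx))
  if (cls$class == "deletion")
    return(sprintf("p.%s%ddel", aa, codon_idx))
  if (cls$class == "insertion")
    return(sprintf("p.%s%dins", aa, codon_idx))
  # SNV: substitute within the codon (plus strand: direct; minus strand:
  # complement the substituted base)
  within <- off %% 3
  newbase <- if (model$strand == "+") alt else reverse_complement(alt)
  mut_codon <- codon
  substr(mut_codon, within + 1, within + 1) <- newbase
  aa2 <- translate_codon(mut_codon)
  if (aa2 == aa) sprintf("p.%s%d=", aa, codon_idx)
  else sprintf("p.%s%d%s", aa, codon_idx, aa2)
}

#' Infer biallelic (functionally homozygous) loss of function
#'
#' A gene is flagged biallelic when at least two distinct
#' loss-of-function calls (frameshift indels or stop gains) each sit in
#' the heterozygous allele-frequency band in the resistant sample. With
#' phasing unknown, two independent heterozygous truncating events are
#' interpreted as hitting both alleles — a functionally homozygous
#' loss.
#'
#' @param calls Call data.frame from [call_discordant_variants()],
#'   optionally with a `protein_effect` column, restricted to one gene.
#' @param gene_id Gene identifier for the summary.
#' @param het_band Allele-frequency interval regarded as heterozygous.
#' @return List with `gene`, `lof_calls` (data.frame), `biallelic`
#'   (logical) and `interpretation` (character).
#' @export
infer_biallelic_loss <- function(calls, gene_id = "gene",
                                 het_band = c(0.3, 0.7)) {
  stop_gain <- if ("protein_effect" %in% names(calls))
    grepl("\\*$", calls$protein_effect) else rep(FALSE, nrow(calls))
  lof <- calls[calls$frameshift | stop_gain, , drop = FALSE]
  in_band <- lof$af_resistant >= het_band[1] & lof$af_resistant <= het_band[2]
  distinct <- !duplicated(paste(lof$pos, lof$ref, lof$alt))
  biallelic <- sum(in_band & distinct) >= 2
  interpretation <- if (biallelic) {
    paste0(gene_id, ": >=2 distinct heterozygous loss-of-function ",
           "variants; compatible with functionally homozygous loss ",
           "(phasing unknown, alleles assumed independently hit)")
  } else if (nrow(lof) == 1) {
    paste0(gene_id, ": single loss-of-function variant; ",
           "mono-allelic (or single homozygous) event")
  } else {
    paste0(gene_id, ": no biallelic loss-of-function pattern")
  }
  list(gene = gene_id, lof_calls = lof, biallelic = biallelic,
       interpretation = interpretation)
}
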