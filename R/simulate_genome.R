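#' Toy genome and gene models for fusion simulation
#'
#' Builds two genes on distinct contigs: a 14-exon "PTPRK-like" 5'
#' partner (`PTPRKL`) and a 4-exon "RSPO3-like" 3' partner (`RSPO3L`),
#' both plus-strand and fully coding. Every exon length is a multiple of
#' 3, so the cumulative CDS length at every exon boundary is divisible
#' by 3: both the exon1->exon2 and the exon13->exon2 junctions between
#' the two genes are in-frame by construction.
#'
#' The exonic sequence of the 5' gene uses only the letters A/C and that
#' of the 3' gene only G/T, so the two transcripts share no k-mer of any
#' length; within each transcript, sequences are redrawn until no k-mer
#' of length `k` repeats. The resulting reference index therefore has no
#' ambiguous seeds. Intron and flanking sequence is unconstrained
#' (transcriptome indexing never touches it).
#'
#' @param seed Integer seed.
#' @param k K-mer size whose within-transcript uniqueness is enforced
#'   (match the [build_reference_index()] `k`).
#' @return List with `genome` (named character vector of contig
#'   sequences) and `models` (named list of two [gene_model()]s,
#'   `PTPRKL` then `RSPO3L`).
#' @export
make_toy_gene_models <- function(seed = 1, k = 21) {
  with_seed(derive_seed(seed, "toy_gene_models"), {
    gene_a <- build_toy_gene("PTPRKL", "chrA", n_exons = 14,
                             alphabet = c("A", "C"), k = k)
    gene_b <- build_toy_gene("RSPO3L", "chrB", n_exons = 4,
                             alphabet = c("G", "T"), k = k)
    list(genome = c(chrA = gene_a$contig_seq, chrB = gene_b$contig_seq),
         models = list(PTPRKL = gene_a$model, RSPO3L = gene_b$model))
  })
}

# One plus-strand gene whose exons all have lengths divisible by 3 and
# whose transcript has unique k-mers; CDS covers every exon.
build_toy_gene <- function(gene_id, contig, n_exons, alphabet, k,
                           max_tries = 50) {
  widths <- sample(seq(90, 210, by = 3), n_exons, replace = TRUE)
  exon_seqs <- NULL
  for (try in seq_len(max_tries)) {
    cand <- vapply(widths, random_dna, character(1), alphabet = alphabet)
    tx <- paste(cand, collapse = "")
    if (!any(duplicated(substring(tx, seq_len(nchar(tx) - k + 1),
                                  seq_len(nchar(tx) - k + 1) + k - 1)))) {
      exon_seqs <- cand
      break
    }
  }
  if (is.null(exon_seqs))
    stop("could not build a transcript with unique ", k, "-mers")
  introns <- vapply(sample(60:150, n_exons + 1, replace = TRUE),
                    random_dna, character(1))
  pieces <- character(2 * n_exons + 1)
  pieces[seq(1, length(pieces), by = 2)] <- introns
  pieces[seq(2, length(pieces), by = 2)] <- exon_seqs
  contig_seq <- paste(pieces, collapse = "")
  starts <- cumsum(c(0, nchar(pieces)))[seq(2, 2 * n_exons, by = 2)]
  exons <- cbind(start = starts, end = starts + widths)
  model <- gene_model(gene_id, contig, "+", exons, cds = exons)
  list(model = model, contig_seq = contig_seq)
}

#' Fused transcript sequence and junction position
#'
#' Joins exons `1..breakpoint5` of the 5' gene to exons
#' `breakpoint3..n` of the 3' gene.
#'
#' @param gene5,gene3 [gene_model()]s.
#' @param breakpoint5 Last retained exon index of the 5' gene.
#' @param breakpoint3 First retained exon index of the 3' gene.
#' @param genome Named character vector of contig sequences.
#' @return List with `sequence` (character) and `junction` (1-based
#'   position of the last 5'-gene base within the fused transcript).
#' @export
fused_transcript <- function(gene5, gene3, breakpoint5, breakpoint3, genome) {
  if (breakpoint5 < 1 || breakpoint5 > nrow(gene5$exons))
    stop("breakpoint5 outside exon range of ", gene5$gene_id)
  if (breakpoint3 < 1 || breakpoint3 > nrow(gene3$exons))
    stop("breakpoint3 outside exon range of ", gene3$gene_id)
  tx5 <- transcript_sequence(gene5, genome)
  tx3 <- transcript_sequence(gene3, genome)
  map5 <- transcript_exon_map(gene5)
  map3 <- transcript_exon_map(gene3)
  j <- map5$tend[breakpoint5]
  keep3_from <- map3$tstart[breakpoint3]
  list(sequence = paste0(substr(tx5, 1, j),
                         substr(tx3, keep3_from, nchar(tx3))),
       junction = j)
}
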