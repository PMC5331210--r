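#' Construct a gene model
#'
#' A lightweight container for a single-transcript gene: an ordered set of
#' exons (and optionally CDS intervals) on one contig. Coordinates are
#' 0-based half-open genomic intervals internally; conversion to the
#' 1-based inclusive GTF convention happens only at I/O boundaries
#' ([read_gtf_models()], [write_gtf_models()]). Exons are stored in
#' transcript (5' to 3') order: ascending genomic start on the plus
#' strand, descending on the minus strand.
#'
#' @param gene_id Gene identifier (unique within a model set).
#' @param contig Contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame (`start`, `end`), 0-based
#'   half-open, one row per exon, in transcript order.
#' @param cds Optional CDS intervals in the same convention; must be
#'   contained in the exons. `NULL` for non-coding models.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- as_intervals(exons, "exons")
  if (any(exons[, 2] <= exons[, 1]))
    stop("gene_model: exon with end <= start in ", gene_id)
  ord <- order(exons[, 1])
  genomic_sorted <- exons[ord, , drop = FALSE]
  if (any(genomic_sorted[-1, 1] < genomic_sorted[-nrow(genomic_sorted), 2]))
    stop("gene_model: overlapping exons in ", gene_id)
  expect_ord <- if (strand == "+") order(exons[, 1]) else order(-exons[, 1])
  if (!identical(expect_ord, seq_len(nrow(exons))))
    stop("gene_model: exons of ", gene_id, " not in transcript order for strand ", strand)
  if (!is.null(cds)) {
    cds <- as_intervals(cds, "cds")
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(contained))
      stop("gene_model: CDS interval outside exons in ", gene_id)
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

as_intervals <- function(x, what) {
  x <- as.matrix(as.data.frame(x))
  if (ncol(x) != 2L) stop("expected two columns (start, end) for ", what)
  storage.mode(x) <- "double"
  colnames(x) <- c("start", "end")
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exon(s), %s\n", x$gene_id, x$contig,
              x$strand, nrow(x$exons),
              if (is.null(x$cds)) "non-coding" else
                sprintf("CDS %d bp", sum(x$cds[, 2] - x$cds[, 1]))))
  invisible(x)
}

exon_widths <- function(model) model$exons[, 2] - model$exons[, 1]

transcript_length <- function(model) sum(exon_widths(model))

#' Exon intervals in transcript coordinates
#'
#' @param model A [gene_model()].
#' @return data.frame with `exon` (1-based index in transcript order),
#'   `tstart`, `tend` (1-based inclusive transcript coordinates).
#' @export
transcript_exon_map <- function(model) {
  w <- exon_widths(model)
  tend <- cumsum(w)
  data.frame(exon = seq_along(w), tstart = tend - w + 1, tend = tend)
}

genome_sequences <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be a named character vector")
    genome
  } else stop("genome must be a named character vector or DNAStringSet")
}

# Extract the genomic substring [start, end) (0-based half-open) on a contig.
contig_slice <- function(genome, contig, start, end) {
  seqs <- genome_sequences(genome)
  if (!contig %in% names(seqs)) stop("unknown contig: ", contig)
  substr(seqs[[contig]], start + 1L, end)
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates the exon sequences in transcript order; on the minus
#' strand each exon is reverse-complemented.
#'
#' @param model A [gene_model()].
#' @param genome Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @return A single character string.
#' @export
transcript_sequence <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- contig_slice(genome, model$contig, model$exons[i, 1], model$exons[i, 2])
    if (model$strand == "-") reverse_complement(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

# Map a 1-based genomic position to a 1-based transcript coordinate, or NA
# if the position is intronic / outside the gene.
genomic_to_transcript <- function(model, pos) {
  pos0 <- pos - 1  # 0-based
  tmap <- transcript_exon_map(model)
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1]; e <- model$exons[i, 2]
    if (pos0 >= s && pos0 < e) {
      off <- if (model$strand == "+") pos0 - s else e - 1 - pos0
      return(unname(tmap$tstart[i] + off))
    }
  }
  NA_real_
}

# CDS intervals mapped to 1-based inclusive transcript coordinates,
# sorted 5' to 3'.
cds_transcript_intervals <- function(model) {
  if (is.null(model$cds)) return(NULL)
  iv <- t(vapply(seq_len(nrow(model$cds)), function(i) {
    a <- genomic_to_transcript(model, model$cds[i, 1] + 1)      # first base
    b <- genomic_to_transcript(model, model$cds[i, 2])          # last base
    sort(c(a, b))
  }, numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  colnames(iv) <- c("tstart", "tend")
  iv
}

# 0-based CDS offset of a 1-based genomic position; NA when non-coding.
cds_offset <- function(model, pos) {
  t <- genomic_to_transcript(model, pos)
  if (is.na(t)) return(NA_real_)
  iv <- cds_transcript_intervals(model)
  if (is.null(iv)) return(NA_real_)
  acc <- 0
  for (i in seq_len(nrow(iv))) {
    if (t >= iv[i, 1] && t <= iv[i, 2]) return(acc + t - iv[i, 1])
    acc <- acc + iv[i, 2] - iv[i, 1] + 1
  }
  NA_real_
}

# Concatenated CDS sequence (reading frame starts at base 1).
cds_sequence <- function(model, genome) {
  iv <- cds_transcript_intervals(model)
  if (is.null(iv)) return(NULL)
  tx <- transcript_sequence(model, genome)
  paste(vapply(seq_len(nrow(iv)), function(i)
    substr(tx, iv[i, 1], iv[i, 2]), character(1)), collapse = "")
}
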