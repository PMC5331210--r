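# Format readers and writers. All on-disk coordinates are 1-based
# inclusive (GTF, VCF, pileup TSV); conversion to the 0-based half-open
# internal convention happens here and only here.

#' Read / write a log2 expression matrix TSV
#'
#' Layout: header row of sample ids, first column of gene ids.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with gene rownames and
#'   sample colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs gene ids plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (any(!is.finite(m))) stop("non-finite expression values in ", path)
  rownames(m) <- genes
  m
}

#' @param expr Matrix as returned by [simulate_cohort_expression()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write stromal signature gene lists
#'
#' One directory holding `CAF.txt`, `Endo.txt`, `Leuco.txt`, one gene
#' symbol per line.
#'
#' @param dir Directory path.
#' @return Named list of character vectors.
#' @export
read_signature_lists <- function(dir) {
  files <- file.path(dir, c(CAF = "CAF.txt", Endo = "Endo.txt",
                            Leuco = "Leuco.txt"))
  missing <- !file.exists(files)
  if (any(missing)) stop("missing signature file(s): ",
                         paste(files[missing], collapse = ", "))
  out <- lapply(files, function(f) {
    g <- readLines(f)
    g <- g[nzchar(g)]
    if (length(g) == 0) stop("empty signature list: ", f)
    g
  })
  names(out) <- c("CAF", "Endo", "Leuco")
  out
}

#' @param signatures Named list (`CAF`, `Endo`, `Leuco`).
#' @rdname read_signature_lists
#' @export
write_signature_lists <- function(signatures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("CAF", "Endo", "Leuco"))
    writeLines(signatures[[nm]], file.path(dir, paste0(nm, ".txt")))
  invisible(dir)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package-wide plain
#' character representation.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' @param sequences Named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  quiet_biostrings(
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path))
  invisible(path)
}

#' Read / write FASTQ reads (Sanger Phred+33)
#'
#' @param path File path.
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # structural pre-check: Biostrings NUL-pads a short quality line
  # instead of failing, so verify the 4-line record layout first
  lines <- readLines(path)
  if (length(lines) == 0 || length(lines) %% 4 != 0)
    stop("malformed FASTQ ", path, ": truncated record")
  sl <- lines[seq(2, length(lines), by = 4)]
  ql <- lines[seq(4, length(lines), by = 4)]
  if (any(nchar(sl) != nchar(ql)))
    stop("malformed FASTQ ", path, ": sequence/quality length mismatch")
  x <- tryCatch(
    quiet_biostrings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e)
      stop("malformed FASTQ ", path, ": ", conditionMessage(e)))
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             row.names = NULL)
}

#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$id
  x <- Biostrings::QualityScaledDNAStringSet(
    s, Biostrings::PhredQuality(reads$quality))
  quiet_biostrings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Read / write gene models as a GTF subset
#'
#' Features `exon` and `CDS` with `gene_id` and `exon_number`
#' attributes; 1-based inclusive on disk, converted to the package's
#' 0-based half-open convention in memory.
#'
#' @param path File path.
#' @return Named list of [gene_model()]s.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0) stop("no exon/CDS features in ", path)
  out <- list()
  for (g in unique(gr$gene_id)) {
    sub <- gr[gr$gene_id == g]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (!strand %in% c("+", "-")) stop("unknown strand for gene ", g)
    ex <- sub[sub$type == "exon"]
    ord <- order(as.integer(ex$exon_number))
    ex <- ex[ord]
    exons <- cbind(start = GenomicRanges::start(ex) - 1,
                   end = GenomicRanges::end(ex))
    cds <- sub[sub$type == "CDS"]
    cds_iv <- if (length(cds) == 0) NULL else
      cbind(start = GenomicRanges::start(cds) - 1,
            end = GenomicRanges::end(cds))
    out[[g]] <- gene_model(g, as.character(GenomicRanges::seqnames(sub))[1],
                           strand, exons, cds = cds_iv)
  }
  out
}

#' @param models Named list of [gene_model()]s.
#' @rdname read_gtf_models
#' @export
write_gtf_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- data.frame(seqnames = m$contig, start = m$exons[, 1] + 1,
                     end = m$exons[, 2], strand = m$strand, type = "exon",
                     gene_id = m$gene_id,
                     exon_number = seq_len(nrow(m$exons)))
    if (!is.null(m$cds)) {
      # exon_number of the exon containing each CDS interval
      cdsn <- vapply(seq_len(nrow(m$cds)), function(i)
        which(m$cds[i, 1] >= m$exons[, 1] & m$cds[i, 2] <= m$exons[, 2])[1],
        integer(1))
      ex <- rbind(ex, data.frame(seqnames = m$contig,
                                 start = m$cds[, 1] + 1, end = m$cds[, 2],
                                 strand = m$strand, type = "CDS",
                                 gene_id = m$gene_id, exon_number = cdsn))
    }
    ex
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::makeGRangesFromDataFrame(df, keep.extra.columns = TRUE)
  suppressWarnings(rtracklayer::export(gr, path, format = "gtf"))
  invisible(path)
}

#' Read / write site-count (pileup) tables
#'
#' TSV columns: `contig`, `pos` (1-based), `ref`, `alt`, `ref_count`,
#' `alt_count`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_pileup_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("pileup table needs columns: ", paste(need, collapse = ", "))
  for (cc in c("contig", "ref", "alt")) df[[cc]] <- as.character(df[[cc]])
  if (any(df$ref_count < 0 | df$alt_count < 0)) stop("negative counts in ", path)
  df
}

#' @param sites Site-count data.frame.
#' @rdname read_pileup_tsv
#' @export
write_pileup_tsv <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write discordant-variant calls as minimal VCF 4.2
#'
#' One record per call with INFO keys `AF_P`, `AF_R`, `FISHER_P`,
#' `CLASS`, `FS`, `PEFF` (when annotated) and `SUPPORT`.
#'
#' @param calls Call data.frame from [call_discordant_variants()],
#'   optionally carrying a `protein_effect` column.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=rspofind-%s", as.character(packageVersion("rspofind"))),
    "##INFO=<ID=AF_P,Number=1,Type=Float,Description=\"Alt allele frequency, parental sample\">",
    "##INFO=<ID=AF_R,Number=1,Type=Float,Description=\"Alt allele frequency, resistant sample\">",
    "##INFO=<ID=FISHER_P,Number=1,Type=Float,Description=\"Two-sided Fisher exact p-value\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"SNV, insertion or deletion\">",
    "##INFO=<ID=FS,Number=0,Type=Flag,Description=\"Frameshift indel\">",
    "##INFO=<ID=PEFF,Number=1,Type=String,Description=\"Protein effect\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Resistant-sample alt read count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    info <- sprintf("AF_P=%.6g;AF_R=%.6g;FISHER_P=%.6g;CLASS=%s%s%s;SUPPORT=%d",
                    calls$af_parental[i], calls$af_resistant[i],
                    calls$fisher_p[i], calls$class[i],
                    if (calls$frameshift[i]) ";FS" else "",
                    if ("protein_effect" %in% names(calls))
                      paste0(";PEFF=", calls$protein_effect[i]) else "",
                    as.integer(calls$support[i]))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$contig[i],
            as.integer(calls$pos[i]), calls$ref[i], calls$alt[i], info)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
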