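#' Build a transcriptome k-mer index
#'
#' Exact k-mer index over the spliced transcript sequences of a set of
#' gene models. K-mers occurring in more than one gene are recorded as
#' ambiguous and never used for seeding; k-mers repeated within one gene
#' keep all their offsets.
#'
#' @param models Named list of [gene_model()]s (unique gene ids).
#' @param genome Named character vector of contig sequences.
#' @param k K-mer length (>= 11; every transcript must be at least k
#'   bases long).
#' @return A `reference_index` object.
#' @export
build_reference_index <- function(models, genome, k = 21) {
  if (k < 11) stop("k must be at least 11")
  ids <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids in model set")
  names(models) <- ids
  transcripts <- vapply(models, transcript_sequence, character(1),
                        genome = genome)
  short <- nchar(transcripts) < k
  if (any(short))
    stop("transcript shorter than k: ", paste(ids[short], collapse = ", "))
  env <- new.env(hash = TRUE, parent = emptyenv())
  owner <- new.env(hash = TRUE, parent = emptyenv())
  ambiguous <- character(0)
  for (g in ids) {
    tx <- transcripts[[g]]
    n <- nchar(tx) - k + 1
    kms <- substring(tx, seq_len(n), seq_len(n) + k - 1)
    for (i in seq_len(n)) {
      km <- kms[i]
      prev_owner <- owner[[km]]
      if (is.null(prev_owner)) {
        owner[[km]] <- g
        env[[km]] <- list(c(gene = g, offset = i))
      } else if (identical(prev_owner, g)) {
        env[[km]] <- c(env[[km]], list(c(gene = g, offset = i)))
      } else if (!identical(prev_owner, "__ambiguous__")) {
        owner[[km]] <- "__ambiguous__"
        rm(list = km, envir = env)
        ambiguous <- c(ambiguous, km)
      }
    }
  }
  structure(list(k = k, env = env, ambiguous = ambiguous,
                 transcripts = transcripts,
                 tx_chars = lapply(transcripts, function(s) strsplit(s, "")[[1]]),
                 genes = ids),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("reference_index: k = %d, %d gene(s), %d ambiguous k-mer(s)\n",
              x$k, length(x$genes), length(x$ambiguous)))
  invisible(x)
}

# Candidate (gene, diagonal) placements of a read obtained from
# unambiguous k-mer seeds. tstart = transcript position of read base 1
# under the diagonal (may be non-positive).
seed_candidates <- function(seq, index) {
  k <- index$k
  L <- nchar(seq)
  if (L < k) return(list())
  n <- L - k + 1
  kms <- substring(seq, seq_len(n), seq_len(n) + k - 1)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (i in seq_len(n)) {
    hits <- index$env[[kms[i]]]
    if (is.null(hits)) next
    for (h in hits) {
      tstart <- as.integer(h[["offset"]]) - i + 1L
      key <- paste0(h[["gene"]], "@", tstart)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- list(gene = h[["gene"]], tstart = tstart)
      }
    }
  }
  out
}

# Mismatch profile of a read against one diagonal: read positions
# pmin..pmax fall inside the transcript; mm[p] is TRUE on mismatch.
diagonal_profile <- function(seq, tx_chars, tstart) {
  L <- nchar(seq)
  tlen <- length(tx_chars)
  pmin <- max(1L, 1L - tstart + 1L)
  pmax <- min(L, tlen - tstart + 1L)
  if (pmin > pmax) return(NULL)
  rp <- pmin:pmax
  rc <- strsplit(seq, "")[[1]][rp]
  tc <- tx_chars[tstart + rp - 1L]
  list(pmin = pmin, pmax = pmax, mm = rc != tc)
}

#' Classify one read: split, linear or unaligned
#'
#' Seed-and-extend split alignment against the transcriptome index. The
#' read prefix and suffix are seeded by unambiguous k-mers; every
#' candidate diagonal is evaluated exactly. A split is reported only
#' when both anchors have at least `min_anchor` bases on their
#' respective read end, the two segments map to two different genes,
#' each segment carries at most `max_mismatch` substitutions, and the
#' segments tile the read within `slack` bases of gap or overlap. Reads
#' fully consistent with a single gene (whole read on one diagonal, at
#' most `max_mismatch` mismatches) are linear; everything else is
#' unaligned. The reverse-complement orientation is always tried; the
#' best placement wins by maximal total matched bases, ties broken by
#' fewer mismatches, then lexicographic gene pair, then smallest
#' junction offset (deterministic). A linear placement beats a split of
#' equal score.
#'
#' @param read Read sequence (character).
#' @param index A [build_reference_index()] index.
#' @param min_anchor Minimum mapped nucleotides per partner on its read
#'   end (default 25, the fusion-calling criterion).
#' @param max_mismatch Maximum substitutions per segment.
#' @param slack Allowed gap/overlap between the two segments.
#' @return List of class `read_alignment` with `type`
#'   (`"split"`/`"linear"`/`"unaligned"`) and, when aligned, the
#'   placement fields (for splits: `gene5`, `gene3`, `anchor5`,
#'   `anchor3`, `breakpoint5`, `breakpoint3`, `mismatch5`, `mismatch3`,
#'   `strand`; for linear: `gene`, `tstart`, `tend`, `mismatches`,
#'   `strand`).
#' @export
align_read_split <- function(read, index, min_anchor = 25,
                             max_mismatch = 2, slack = 0) {
  best_linear <- NULL
  best_split <- NULL
  tx_cache <- index$tx_chars
  for (orient in c("+", "-")) {
    seq <- if (orient == "+") read else reverse_complement(read)
    L <- nchar(seq)
    cands <- seed_candidates(seq, index)
    if (length(cands) == 0) next
    profs <- lapply(cands, function(cd) {
      pr <- diagonal_profile(seq, tx_cache[[cd$gene]], cd$tstart)
      if (is.null(pr)) NULL else c(cd, pr)
    })
    profs <- Filter(Negate(is.null), profs)
    # linear candidates: full-length coverage
    for (pr in profs) {
      if (pr$pmin == 1L && pr$pmax == L) {
        mmtot <- sum(pr$mm)
        if (mmtot <= max_mismatch) {
          score <- L - mmtot
          cand <- list(type = "linear", gene = pr$gene,
                       tstart = pr$tstart, tend = pr$tstart + L - 1L,
                       mismatches = mmtot, strand = orient, score = score)
          if (is.null(best_linear) || better_placement(cand, best_linear))
            best_linear <- cand
        }
      }
    }
    # split candidates: prefix (anchored at read base 1) x suffix
    # (anchored at read base L)
    prefixes <- Filter(function(pr) pr$pmin == 1L, profs)
    suffixes <- Filter(function(pr) pr$pmax == L, profs)
    for (p5 in prefixes) {
      cm5 <- cumsum(p5$mm)                       # mismatches in read[1..p]
      for (p3 in suffixes) {
        if (p5$gene == p3$gene) next
        cm3 <- rev(cumsum(rev(p3$mm)))           # mismatches in read[p..L]
        # junction after read position a (5' anchor length a), suffix
        # starts at read position b; gap = b - a - 1 in [-slack, slack]
        a_hi <- min(p5$pmax, L - min_anchor)
        if (a_hi < min_anchor) next
        for (a in min_anchor:a_hi) {
          if (cm5[a] > max_mismatch) break
          if (p5$mm[a]) next  # junction-side segment end must match
          b_lo <- max(p3$pmin, a + 1 - slack)
          b_hi <- min(a + 1 + slack, L - min_anchor + 1)
          if (b_lo > b_hi) next
          for (b in b_lo:b_hi) {
            if (p3$mm[b - p3$pmin + 1L]) next  # junction-side start must match
            m3 <- cm3[b - p3$pmin + 1L]
            if (m3 > max_mismatch) next
            anchor3 <- L - b + 1L
            score <- (a - cm5[a]) + (anchor3 - m3)
            cand <- list(type = "split", gene5 = p5$gene, gene3 = p3$gene,
                         anchor5 = a, anchor3 = anchor3,
                         breakpoint5 = p5$tstart + a - 1L,
                         breakpoint3 = p3$tstart + b - 1L,
                         mismatch5 = cm5[a], mismatch3 = m3,
                         strand = orient, score = score)
            if (is.null(best_split) || better_placement(cand, best_split))
              best_split <- cand
          }
        }
      }
    }
  }
  res <- if (!is.null(best_split) &&
             (is.null(best_linear) || best_split$score > best_linear$score)) {
    best_split
  } else if (!is.null(best_linear)) {
    best_linear
  } else {
    list(type = "unaligned")
  }
  structure(res, class = "read_alignment")
}

# Deterministic preference order between two placements of equal type.
better_placement <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  mma <- sum(unlist(a[c("mismatches", "mismatch5", "mismatch3")]))
  mmb <- sum(unlist(b[c("mismatches", "mismatch5", "mismatch3")]))
  if (mma != mmb) return(mma < mmb)
  ka <- paste(a$gene5 %||% a$gene, a$gene3 %||% "", a$breakpoint5 %||% a$tstart)
  kb <- paste(b$gene5 %||% b$gene, b$gene3 %||% "", b$breakpoint5 %||% b$tstart)
  ka < kb
}

#' Align a set of reads
#'
#' @param reads data.frame with `id` and `sequence` columns (e.g. from
#'   [simulate_fusion_reads()] or [read_fastq()]).
#' @param index A [build_reference_index()] index.
#' @inheritParams align_read_split
#' @return Named list of `read_alignment` objects (names = read ids).
#' @export
align_reads <- function(reads, index, min_anchor = 25, max_mismatch = 2,
                        slack = 0) {
  out <- lapply(reads$sequence, align_read_split, index = index,
                min_anchor = min_anchor, max_mismatch = max_mismatch,
                slack = slack)
  names(out) <- reads$id
  out
}

#' Cluster split alignments into fusion calls
#'
#' Splits are clustered by the exact breakpoint pair
#' (gene5, breakpoint5, gene3, breakpoint3); cluster size is the
#' supporting-read count. Each call is annotated with the exon index
#' containing each breakpoint, whether both breakpoints coincide with
#' annotated exon boundaries, and the reading-frame status
#' ([annotate_frame()]). Calls are sorted by descending support.
#'
#' @param alignments List of `read_alignment` objects.
#' @param models Named list of [gene_model()]s.
#' @param min_support Minimum supporting reads per call (default 2).
#' @return data.frame with columns `gene5`, `exon5`, `breakpoint5`,
#'   `gene3`, `exon3`, `breakpoint3`, `support`, `frame`, `boundary`.
#' @export
call_fusions <- function(alignments, models, min_support = 2) {
  empty <- data.frame(gene5 = character(0), exon5 = integer(0),
                      breakpoint5 = integer(0), gene3 = character(0),
                      exon3 = integer(0), breakpoint3 = integer(0),
                      support = integer(0), frame = character(0),
                      boundary = character(0))
  splits <- Filter(function(a) a$type == "split", alignments)
  if (length(splits) == 0) return(empty)
  key <- vapply(splits, function(a)
    paste(a$gene5, a$breakpoint5, a$gene3, a$breakpoint3, sep = "|"),
    character(1))
  tab <- table(key)
  tab <- tab[tab >= min_support]
  if (length(tab) == 0) return(empty)
  rows <- lapply(names(tab), function(kk) {
    f <- strsplit(kk, "|", fixed = TRUE)[[1]]
    g5 <- f[1]; bp5 <- as.integer(f[2]); g3 <- f[3]; bp3 <- as.integer(f[4])
    m5 <- transcript_exon_map(models[[g5]])
    m3 <- transcript_exon_map(models[[g3]])
    e5 <- m5$exon[bp5 >= m5$tstart & bp5 <= m5$tend]
    e3 <- m3$exon[bp3 >= m3$tstart & bp3 <= m3$tend]
    boundary <- if (length(e5) == 1 && length(e3) == 1 &&
                    bp5 == m5$tend[e5] && bp3 == m3$tstart[e3])
      "at-exon-boundary" else "internal"
    data.frame(gene5 = g5, exon5 = if (length(e5)) e5 else NA_integer_,
               breakpoint5 = bp5, gene3 = g3,
               exon3 = if (length(e3)) e3 else NA_integer_,
               breakpoint3 = bp3, support = as.integer(tab[[kk]]),
               frame = annotate_frame(g5, bp5, g3, bp3, models),
               boundary = boundary)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$gene5, out$gene3, out$breakpoint5), ]
  rownames(out) <- NULL
  out
}

#' Reading-frame status of a fusion junction
#'
#' The junction is in-frame when the CDS length retained upstream of the
#' 5' breakpoint and the CDS offset discarded upstream of the 3'
#' breakpoint are congruent modulo 3. Genes without CDS annotation (or
#' junctions outside the coding region) are non-coding.
#'
#' @param gene5,gene3 Gene ids.
#' @param breakpoint5,breakpoint3 1-based transcript coordinates: last
#'   retained base of the 5' transcript, first retained base of the 3'
#'   transcript.
#' @param models Named list of [gene_model()]s.
#' @return `"in-frame"`, `"out-of-frame"` or `"non-coding"`.
#' @export
annotate_frame <- function(gene5, breakpoint5, gene3, breakpoint3, models) {
  g5 <- models[[gene5]]; g3 <- models[[gene3]]
  if (is.null(g5) || is.null(g3)) stop("unknown gene in fusion call")
  if (breakpoint5 < 1 || breakpoint5 > transcript_length(g5) ||
      breakpoint3 < 1 || breakpoint3 > transcript_length(g3))
    stop("breakpoint outside transcript")
  iv5 <- cds_transcript_intervals(g5)
  iv3 <- cds_transcript_intervals(g3)
  if (is.null(iv5) || is.null(iv3)) return("non-coding")
  retained <- cds_bases_upto(iv5, breakpoint5)
  if (retained == 0) return("non-coding")
  discarded <- cds_bases_upto(iv3, breakpoint3 - 1)
  if (breakpoint3 > max(iv3[, 2])) return("non-coding")
  if (retained %% 3 == discarded %% 3) "in-frame" else "out-of-frame"
}

# CDS bases at transcript coordinates <= t.
cds_bases_upto <- function(iv, t) {
  sum(pmax(0, pmin(iv[, 2], t) - iv[, 1] + 1))
}

#' Per-exon read coverage of one gene
#'
#' Counts reads and aligned bases overlapping each exon of a gene, in
#' transcript coordinates. Split reads contribute only the segment that
#' maps to this gene; linear reads contribute their full span. The
#' `exon1_absent` attribute flags a gene whose first exon receives no
#' reads — the signature of a locus expressed exclusively through a
#' fusion transcript.
#'
#' @param alignments List of `read_alignment` objects.
#' @param model A [gene_model()].
#' @return data.frame (`exon`, `n_reads`, `n_bases`) with logical
#'   attribute `exon1_absent`.
#' @export
exon_coverage <- function(alignments, model) {
  tmap <- transcript_exon_map(model)
  g <- model$gene_id
  spans <- list()
  for (a in alignments) {
    if (a$type == "linear" && identical(a$gene, g)) {
      spans[[length(spans) + 1L]] <- c(a$tstart, a$tend)
    } else if (a$type == "split") {
      if (identical(a$gene5, g))
        spans[[length(spans) + 1L]] <- c(a$breakpoint5 - a$anchor5 + 1L,
                                         a$breakpoint5)
      if (identical(a$gene3, g))
        spans[[length(spans) + 1L]] <- c(a$breakpoint3,
                                         a$breakpoint3 + a$anchor3 - 1L)
    }
  }
  n_reads <- integer(nrow(tmap)); n_bases <- integer(nrow(tmap))
  for (sp in spans) {
    ov_lo <- pmax(tmap$tstart, sp[1]); ov_hi <- pmin(tmap$tend, sp[2])
    hit <- ov_hi >= ov_lo
    n_reads <- n_reads + hit
    n_bases <- n_bases + ifelse(hit, ov_hi - ov_lo + 1L, 0L)
  }
  out <- data.frame(exon = tmap$exon, n_reads = n_reads, n_bases = n_bases)
  attr(out, "exon1_absent") <- n_reads[1] == 0L
  out
}
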