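#' Specification for the junction-read simulator
#'
#' @param gene5,gene3 Gene ids of the fusion partners (must exist in the
#'   model set handed to [simulate_fusion_reads()]).
#' @param breakpoint5 Last retained exon of the 5' gene.
#' @param breakpoint3 First retained exon of the 3' gene.
#' @param n_junction_reads Number of junction-spanning reads; ignored
#'   (and inferred) when `anchor_length_list` is given.
#' @param anchor_length_list Optional integer vector: per-read offset of
#'   the junction within the read, i.e. the 5' anchor length. Each value
#'   must lie in `[1, read_length - 1]`. `NULL` draws offsets uniformly.
#' @param n_wildtype_reads Named or unnamed length-2 vector: wild-type
#'   read counts for the (unfused) 5' and 3' transcripts.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability.
#' @param base_quality Constant Phred quality assigned to every base.
#' @param low_quality_fraction Fraction of bases demoted to Phred
#'   `low_quality_value` (exercises the quality-masking rule of the
#'   variant module).
#' @param low_quality_value Phred value for demoted bases.
#' @param seed Integer seed.
#' @return A `fusion_sim_spec` list.
#' @export
fusion_sim_spec <- function(gene5 = "PTPRKL", gene3 = "RSPO3L",
                            breakpoint5 = 1, breakpoint3 = 2,
                            n_junction_reads = 30,
                            anchor_length_list = NULL,
                            n_wildtype_reads = c(0, 0),
                            read_length = 75, error_rate = 0,
                            base_quality = 35, low_quality_fraction = 0,
                            low_quality_value = 10, seed = 1) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (read_length < 2) stop("read_length must be at least 2")
  if (!is.null(anchor_length_list)) {
    if (any(anchor_length_list < 1 | anchor_length_list > read_length - 1))
      stop("anchor offsets must lie in [1, read_length - 1]")
    n_junction_reads <- length(anchor_length_list)
  }
  structure(list(gene5 = gene5, gene3 = gene3, breakpoint5 = breakpoint5,
                 breakpoint3 = breakpoint3,
                 n_junction_reads = n_junction_reads,
                 anchor_length_list = anchor_length_list,
                 n_wildtype_reads = rep_len(n_wildtype_reads, 2),
                 read_length = read_length, error_rate = error_rate,
                 base_quality = base_quality,
                 low_quality_fraction = low_quality_fraction,
                 low_quality_value = low_quality_value,
                 seed = as.integer(seed)),
            class = "fusion_sim_spec")
}

#' Simulate junction-spanning and wild-type RNA-seq reads
#'
#' Junction reads are exact windows of the fused transcript placed so
#' that the junction falls at each requested offset; wild-type reads
#' sample each unfused transcript uniformly. Substitution errors are
#' applied at `error_rate`; qualities follow a constant-Phred model
#' (with an optional low-quality fraction). The truth table
#' records, per junction read, the true 5' and 3' anchor lengths and
#' their minimum.
#'
#' @param spec A [fusion_sim_spec()].
#' @param models Named list of [gene_model()]s.
#' @param genome Named character vector of contig sequences.
#' @return List with `reads` (data.frame: `id`, `sequence`, `quality`)
#'   and `truth` (data.frame over junction reads: `id`, `anchor5`,
#'   `anchor3`, `min_anchor`, `n_errors`).
#' @export
simulate_fusion_reads <- function(spec, models, genome) {
  stopifnot(inherits(spec, "fusion_sim_spec"))
  if (!spec$gene5 %in% names(models) || !spec$gene3 %in% names(models))
    stop("fusion partner genes missing from the model set")
  g5 <- models[[spec$gene5]]; g3 <- models[[spec$gene3]]
  ft <- fused_transcript(g5, g3, spec$breakpoint5, spec$breakpoint3, genome)
  L <- spec$read_length

  anchors <- spec$anchor_length_list
  if (is.null(anchors) && spec$n_junction_reads > 0)
    anchors <- with_seed(derive_seed(spec$seed, "anchors"),
                         sample.int(L - 1, spec$n_junction_reads,
                                    replace = TRUE))
  anchors <- anchors %||% integer(0)

  jseq <- vapply(anchors, function(a) {
    start <- ft$junction - a + 1
    if (start < 1 || start + L - 1 > nchar(ft$sequence))
      stop("junction read with anchor ", a,
           " does not fit inside the fused transcript")
    substr(ft$sequence, start, start + L - 1)
  }, character(1))
  jids <- sprintf("junc_%03d", seq_along(anchors))

  wt <- with_seed(derive_seed(spec$seed, "wildtype"), {
    out <- list(seq = character(0), id = character(0))
    for (gi in 1:2) {
      gname <- c(spec$gene5, spec$gene3)[gi]
      n <- spec$n_wildtype_reads[gi]
      if (n == 0) next
      tx <- transcript_sequence(models[[gname]], genome)
      if (nchar(tx) < L) stop("transcript of ", gname, " shorter than read length")
      st <- sample.int(nchar(tx) - L + 1, n, replace = TRUE)
      out$seq <- c(out$seq, substring(tx, st, st + L - 1))
      out$id <- c(out$id, sprintf("wt_%s_%03d", gname, seq_len(n)))
    }
    out
  })

  seqs <- c(jseq, wt$seq)
  ids <- c(jids, wt$id)
  n_err <- integer(length(seqs))
  if (length(seqs) > 0 && spec$error_rate > 0) {
    seqs <- with_seed(derive_seed(spec$seed, "errors"), {
      vapply(seq_along(seqs), function(i) {
        ch <- strsplit(seqs[i], "")[[1]]
        hit <- which(runif(length(ch)) < spec$error_rate)
        n_err[i] <<- length(hit)
        for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        paste(ch, collapse = "")
      }, character(1))
    })
  }

  quals <- with_seed(derive_seed(spec$seed, "qualities"), {
    vapply(seq_along(seqs), function(i) {
      q <- rep(spec$base_quality, L)
      if (spec$low_quality_fraction > 0) {
        n_low <- round(spec$low_quality_fraction * L)
        if (n_low > 0) q[sample.int(L, n_low)] <- spec$low_quality_value
      }
      phred_to_char(q)
    }, character(1))
  })

  truth <- data.frame(id = jids,
                      anchor5 = as.integer(anchors),
                      anchor3 = as.integer(L - anchors),
                      min_anchor = as.integer(pmin(anchors, L - anchors)),
                      n_errors = n_err[seq_along(jids)])
  list(reads = data.frame(id = ids, sequence = seqs, quality = quals),
       truth = truth)
}
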