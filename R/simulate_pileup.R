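#' Specification for the paired-pileup simulator
#'
#' @param n_sites Number of background (non-variant) sites.
#' @param depth_parental,depth_resistant Mean sequencing depths; per-site
#'   depths are Poisson with these means.
#' @param planted_variants Optional data.frame describing planted
#'   variants with columns `pos`, `ref`, `alt` (VCF-style alleles, so a
#'   1-bp deletion is e.g. ref `"AG"`, alt `"A"`), `af_parental`,
#'   `af_resistant`, and optionally per-site `depth_parental` /
#'   `depth_resistant` overrides.
#' @param error_floor Alt-allele frequency at non-variant sites
#'   (sequencing-error background; default 0).
#' @param contig Contig name for generated sites.
#' @param positions Optional explicit positions of the background sites.
#' @param ref_bases Optional reference bases for the background sites
#'   (e.g. drawn from a genome); random otherwise.
#' @param seed Integer seed.
#' @return A `pileup_sim_spec` list.
#' @export
pileup_sim_spec <- function(n_sites = 100, depth_parental = 150,
                            depth_resistant = 150, planted_variants = NULL,
                            error_floor = 0, contig = "chrV",
                            positions = NULL, ref_bases = NULL, seed = 1) {
  if (!is.null(planted_variants)) {
    planted_variants <- as.data.frame(planted_variants)
    need <- c("pos", "ref", "alt", "af_parental", "af_resistant")
    if (!all(need %in% names(planted_variants)))
      stop("planted_variants needs columns: ", paste(need, collapse = ", "))
    af <- c(planted_variants$af_parental, planted_variants$af_resistant)
    if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0, 1]")
  }
  if (error_floor < 0 || error_floor > 1) stop("error_floor must be in [0, 1]")
  structure(list(n_sites = n_sites, depth_parental = depth_parental,
                 depth_resistant = depth_resistant,
                 planted_variants = planted_variants,
                 error_floor = error_floor, contig = contig,
                 positions = positions, ref_bases = ref_bases,
                 seed = as.integer(seed)),
            class = "pileup_sim_spec")
}

#' Simulate paired parental/resistant pileup tables
#'
#' Per-site depths are Poisson around the configured means and alt
#' counts Binomial(depth, AF). Non-planted sites have alt frequency
#' `error_floor` in both samples (0 by default). Deterministic under the
#' spec seed.
#'
#' @param spec A [pileup_sim_spec()].
#' @return List with `parental` and `resistant` site-count data.frames
#'   (`contig`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`) and
#'   `truth` (the planted-variant table with the simulated counts and a
#'   `resistant_specific` flag).
#' @export
simulate_paired_pileup <- function(spec) {
  stopifnot(inherits(spec, "pileup_sim_spec"))
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(spec$seed, "paired_pileup"), {
    pos <- spec$positions %||%
      (if (spec$n_sites > 0) seq(1000, by = 137, length.out = spec$n_sites)
       else numeric(0))
    ref <- spec$ref_bases %||% sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)
    af_p <- rep(spec$error_floor, length(pos))
    af_r <- rep(spec$error_floor, length(pos))
    dp_mean <- rep(spec$depth_parental, length(pos))
    dr_mean <- rep(spec$depth_resistant, length(pos))

    pv <- spec$planted_variants
    if (!is.null(pv) && nrow(pv) > 0) {
      pos <- c(pos, pv$pos); ref <- c(ref, pv$ref); alt <- c(alt, pv$alt)
      af_p <- c(af_p, pv$af_parental); af_r <- c(af_r, pv$af_resistant)
      dp_mean <- c(dp_mean, pv$depth_parental %||%
                     rep(spec$depth_parental, nrow(pv)))
      dr_mean <- c(dr_mean, pv$depth_resistant %||%
                     rep(spec$depth_resistant, nrow(pv)))
    }
    ord <- order(pos)
    pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    af_p <- af_p[ord]; af_r <- af_r[ord]
    dp_mean <- dp_mean[ord]; dr_mean <- dr_mean[ord]
    planted <- ord > length(af_p) - (if (is.null(pv)) 0 else nrow(pv))

    depth_p <- pmax(1L, rpois(length(pos), dp_mean))
    depth_r <- pmax(1L, rpois(length(pos), dr_mean))
    alt_p <- rbinom(length(pos), depth_p, af_p)
    alt_r <- rbinom(length(pos), depth_r, af_r)

    mk <- function(depth, altc) data.frame(
      contig = rep(spec$contig, length(pos)), pos = pos, ref = ref,
      alt = alt, ref_count = depth - altc, alt_count = altc)
    truth <- data.frame(contig = rep(spec$contig, sum(planted)),
                        pos = pos[planted], ref = ref[planted],
                        alt = alt[planted],
                        af_parental = af_p[planted],
                        af_resistant = af_r[planted],
                        alt_count_parental = alt_p[planted],
                        alt_count_resistant = alt_r[planted])
    if (nrow(truth) > 0) {
      cls <- t(vapply(seq_len(nrow(truth)), function(i)
        unlist(classify_indel(truth$ref[i], truth$alt[i])[c("class", "frameshift")]),
        character(2)))
      truth$class <- cls[, 1]
      truth$frameshift <- as.logical(cls[, 2])
      truth$resistant_specific <- truth$af_resistant > 0 & truth$af_parental == 0
    }
    list(parental = mk(depth_p, alt_p), resistant = mk(depth_r, alt_r),
         truth = truth)
  })
}

#' Toy AXIN1-like coding gene model
#'
#' A single-exon, fully coding 2520-bp gene (840 codons) on its own
#' contig, engineered so that codon 265 encodes glycine and codon 835
#' encodes valine. Used by [axin_resistance_fixture()] to reproduce the
#' structure of a resistant clone carrying two independent heterozygous
#' frameshift deletions in one WNT-inhibitor gene.
#'
#' @param seed Integer seed.
#' @return List with `genome` (named character) and `model`
#'   (a [gene_model()] named `AXIN1L`).
#' @export
make_axin_like_model <- function(seed = 1) {
  with_seed(derive_seed(seed, "axin_like"), {
    n_codons <- 840
    cds <- random_dna(3 * n_codons)
    put_codon <- function(s, codon_idx, triplet) {
      paste0(substr(s, 1, 3 * (codon_idx - 1)), triplet,
             substr(s, 3 * codon_idx + 1, nchar(s)))
    }
    cds <- put_codon(cds, 1, "ATG")
    cds <- put_codon(cds, 265, "GGA")  # glycine
    cds <- put_codon(cds, 835, "GTC")  # valine
    # no internal stop codons are required for annotation; leave as drawn
    pad5 <- random_dna(100); pad3 <- random_dna(100)
    contig <- paste0(pad5, cds, pad3)
    exons <- cbind(start = 100, end = 100 + nchar(cds))
    model <- gene_model("AXIN1L", "chrAX", "+", exons, cds = exons)
    list(genome = c(chrAX = contig), model = model)
  })
}

#' Packaged two-deletion resistance fixture
#'
#' Builds the AXIN1-like gene model and a paired pileup in which the
#' resistant sample carries two distinct heterozygous single-base
#' deletions inside the coding sequence (in codons 265 and 835) that are
#' absent from the parental sample, alongside clean background sites.
#' Mean depths at the two variant sites default to 66 and 180 so that at
#' heterozygous allele frequency the expected alt support is 33 and 90
#' reads.
#'
#' @param seed Integer seed.
#' @param n_background Background (non-variant) sites.
#' @param af_resistant Heterozygous allele frequency of both deletions in
#'   the resistant sample.
#' @return List with `genome`, `model`, `spec` (the [pileup_sim_spec()])
#'   and the [simulate_paired_pileup()] output (`parental`, `resistant`,
#'   `truth`).
#' @export
axin_resistance_fixture <- function(seed = 1, n_background = 50,
                                    af_resistant = 0.5) {
  ax <- make_axin_like_model(seed)
  genome_seq <- ax$genome[["chrAX"]]
  # genomic 1-based position of the first base of a codon (plus strand,
  # single exon starting at 0-based 100)
  codon_pos <- function(codon_idx) 100 + 3 * (codon_idx - 1) + 1
  del_site <- function(codon_idx) {
    p <- codon_pos(codon_idx)
    c(pos = p - 1,
      ref = substr(genome_seq, p - 1, p),
      alt = substr(genome_seq, p - 1, p - 1))
  }
  s1 <- del_site(265); s2 <- del_site(835)
  planted <- data.frame(
    pos = as.numeric(c(s1["pos"], s2["pos"])),
    ref = c(s1["ref"], s2["ref"]),
    alt = c(s1["alt"], s2["alt"]),
    af_parental = c(0, 0),
    af_resistant = rep(af_resistant, 2),
    depth_parental = c(66, 180),
    depth_resistant = c(66, 180))
  span <- range(ax$model$exons)
  positions <- seq(span[1] + 5, span[2] - 5, length.out = n_background)
  positions <- setdiff(round(positions), planted$pos)
  spec <- pileup_sim_spec(
    n_sites = length(positions), planted_variants = planted,
    contig = "chrAX", positions = positions,
    ref_bases = substring(genome_seq, positions, positions),
    depth_parental = 150, depth_resistant = 150, seed = seed)
  sim <- simulate_paired_pileup(spec)
  c(list(genome = ax$genome, model = ax$model, spec = spec), sim)
}
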