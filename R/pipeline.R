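#' Pipeline configuration
#'
#' A single list (optionally loaded from JSON) holding stage selection,
#' stage thresholds, the seed and the output directory. Every run echoes
#' its configuration into the run log.
#'
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "score", "fuse", "variants")`.
#' @param seed Integer seed used by every simulation stage.
#' @param z_expr,z_delta Outlier thresholds ([delta_outlier_analysis()]).
#' @param min_anchor,min_support Fusion-calling thresholds.
#' @param min_af,alpha,min_depth Variant-calling thresholds.
#' @param phred_threshold Base-quality masking threshold.
#' @param cohort Named list of [cohort_sim_config()] overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, stages = c("simulate", "score",
                                                "fuse", "variants"),
                            seed = 1, z_expr = 2, z_delta = 2.5,
                            min_anchor = 25, min_support = 2,
                            min_af = 0.015, alpha = 0.05, min_depth = 20,
                            phred_threshold = 20, cohort = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(z_expr > 0, z_delta > 0, min_anchor >= 1, min_support >= 1,
            min_af >= 0, min_af <= 1, alpha > 0, alpha <= 1)
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 z_expr = z_expr, z_delta = z_delta,
                 min_anchor = min_anchor, min_support = min_support,
                 min_af = min_af, alpha = alpha, min_depth = min_depth,
                 phred_threshold = phred_threshold, cohort = cohort),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Keys mirror the [pipeline_config()] arguments; absent keys keep their
#' defaults, and explicit arguments passed through `...` override the
#' file.
#'
#' @param path JSON file.
#' @param ... Overrides.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such config file: ", path)
  keys <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys[names(list(...))] <- list(...)
  do.call(pipeline_config, keys)
}

#' Run the full synthetic-data demonstration pipeline
#'
#' Executes, as configured: cohort simulation and its outlier scoring;
#' toy-genome fusion-read simulation, split-read alignment and fusion
#' calling; the two-deletion resistance pileup fixture and discordant
#' variant calling with protein-effect and biallelic loss-of-function
#' annotation. All artifacts are written under `config$out_dir` along
#' with a JSON run log recording the package version, seed, thresholds
#' and per-artifact MD5 checksums. Deterministic under the configured
#' seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success), `artifacts`
#'   (named paths) and `log` (path of the run log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  if ("simulate" %in% config$stages || "score" %in% config$stages) {
    cohort_args <- config$cohort
    cohort_args$seed <- cohort_args$seed %||% config$seed
    cohort <- simulate_cohort_expression(do.call(cohort_sim_config, cohort_args))
    art$expression <- write_expression_tsv(
      cohort$expr, file.path(config$out_dir, "expression.tsv"))
    art$signatures <- write_signature_lists(
      cohort$signatures, file.path(config$out_dir, "signatures"))
    art$cohort_truth <- file.path(config$out_dir, "cohort_truth.tsv")
    write.table(cohort$truth$samples, art$cohort_truth, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if ("score" %in% config$stages) {
    expr <- read_expression_tsv(art$expression)
    sigs <- read_signature_lists(art$signatures)
    scores <- compute_stromal_scores(expr, sigs)
    target <- config$cohort$target_gene %||% "RSPO3"
    report <- delta_outlier_analysis(expr, target, scores,
                                     z_expr = config$z_expr,
                                     z_delta = config$z_delta)
    art$outlier_report <- file.path(config$out_dir, "outlier_report.tsv")
    write.table(report, art$outlier_report, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if ("fuse" %in% config$stages) {
    toy <- make_toy_gene_models(seed = config$seed)
    art$genome <- write_fasta(toy$genome, file.path(config$out_dir, "genome.fa"))
    art$models <- write_gtf_models(toy$models,
                                   file.path(config$out_dir, "models.gtf"))
    spec <- fusion_sim_spec(n_junction_reads = 30,
                            n_wildtype_reads = c(40, 0), seed = config$seed)
    sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
    art$reads <- write_fastq(sim$reads, file.path(config$out_dir, "reads.fastq"))
    idx <- build_reference_index(toy$models, toy$genome)
    aln <- align_reads(read_fastq(art$reads), idx,
                       min_anchor = config$min_anchor)
    calls <- call_fusions(aln, toy$models, min_support = config$min_support)
    art$fusions <- file.path(config$out_dir, "fusions.tsv")
    write.table(calls, art$fusions, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cov <- exon_coverage(aln, toy$models$RSPO3L)
    art$exon_coverage <- file.path(config$out_dir, "exon_coverage.tsv")
    write.table(cov, art$exon_coverage, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if ("variants" %in% config$stages) {
    fx <- axin_resistance_fixture(seed = config$seed)
    art$pileup_parental <- write_pileup_tsv(
      fx$parental, file.path(config$out_dir, "pileup_parental.tsv"))
    art$pileup_resistant <- write_pileup_tsv(
      fx$resistant, file.path(config$out_dir, "pileup_resistant.tsv"))
    calls <- call_discordant_variants(
      read_pileup_tsv(art$pileup_parental),
      read_pileup_tsv(art$pileup_resistant),
      min_af = config$min_af, alpha = config$alpha,
      min_depth = config$min_depth)
    if (nrow(calls) > 0)
      calls$protein_effect <- vapply(seq_len(nrow(calls)), function(i)
        annotate_protein_effect(calls[i, ], fx$model, fx$genome), character(1))
    art$variants <- write_variants_vcf(
      calls, file.path(config$out_dir, "variants.vcf"))
    lof <- infer_biallelic_loss(calls, gene_id = fx$model$gene_id)
    art$lof_summary <- file.path(config$out_dir, "lof_summary.tsv")
    write.table(data.frame(gene = lof$gene, biallelic = lof$biallelic,
                           n_lof = nrow(lof$lof_calls),
                           interpretation = lof$interpretation),
                art$lof_summary, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- unlist(art, use.names = TRUE)
  files <- files[file.exists(files) & !dir.exists(files)]
  log <- list(version = as.character(packageVersion("rspofind")),
              started = t0,
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed,
              thresholds = config[c("z_expr", "z_delta", "min_anchor",
                                    "min_support", "min_af", "alpha",
                                    "min_depth", "phred_threshold")],
              stages = config$stages,
              checksums = as.list(tools::md5sum(files)))
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(status = 0L, artifacts = art, log = log_path))
}
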