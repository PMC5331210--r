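#' Configuration for the stromally confounded expression-cohort simulator
#'
#' The generative model is a two-component mixture on the linear scale
#' observed in log2 with Gaussian noise. Each sample i carries a stromal
#' fraction f_i ~ Beta(a, b). A stromal-signature gene g (CAF,
#' endothelial or leukocyte class) has expression
#' `log2(1 + S_g * f_i) + N(0, noise_sd)` with a fixed per-gene
#' coefficient S_g drawn log-uniformly on `[100, 2000]`. The target gene
#' adds an epithelial component in fusion-positive samples:
#' `log2(1 + S_t * f_i + E * fused_i) + N(0, noise_sd)`. Background genes
#' are independent of f_i. Planted fused samples draw their stromal
#' fraction from `fused_purity_range` (default: the lower tertile of the
#' Beta distribution, i.e. fusion carriers tend to be low-stroma).
#'
#' Defaults mirror the scale of the motivating 450-sample TCGA colorectal
#' RNA-seq analysis with 6 fusion-positive samples.
#'
#' @param n_samples Number of samples.
#' @param n_signature_genes Genes per stromal signature class.
#' @param n_background_genes Stroma-independent background genes.
#' @param stromal_beta Length-2 vector, Beta(a, b) parameters of the
#'   stromal fraction distribution.
#' @param target_gene Name of the target gene row.
#' @param stromal_coefficient_target S_t, linear-scale expression of the
#'   target per unit stromal fraction.
#' @param epithelial_overexpr_level E, linear-scale expression added in
#'   fusion-positive samples.
#' @param n_fused Number of planted fusion-positive samples.
#' @param fused_purity_range Interval of stromal fraction from which
#'   planted fused samples draw f_i (truncated Beta). `NULL` selects the
#'   lower tertile of the configured Beta.
#' @param noise_sd Gaussian observation noise, log2 units.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_samples = 450, n_signature_genes = 30,
                              n_background_genes = 100,
                              stromal_beta = c(2, 2),
                              target_gene = "RSPO3",
                              stromal_coefficient_target = 500,
                              epithelial_overexpr_level = 1500,
                              n_fused = 6, fused_purity_range = NULL,
                              noise_sd = 0.3, seed = 1) {
  if (n_fused > n_samples) stop("n_fused must not exceed n_samples")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(stromal_beta <= 0)) stop("Beta parameters must be positive")
  if (is.null(fused_purity_range))
    fused_purity_range <- c(0, qbeta(1 / 3, stromal_beta[1], stromal_beta[2]))
  if (fused_purity_range[1] < 0 || fused_purity_range[2] > 1 ||
      fused_purity_range[1] >= fused_purity_range[2])
    stop("fused_purity_range must be a sub-interval of [0, 1]")
  structure(list(n_samples = n_samples,
                 n_signature_genes = n_signature_genes,
                 n_background_genes = n_background_genes,
                 stromal_beta = stromal_beta, target_gene = target_gene,
                 stromal_coefficient_target = stromal_coefficient_target,
                 epithelial_overexpr_level = epithelial_overexpr_level,
                 n_fused = n_fused, fused_purity_range = fused_purity_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

rbeta_trunc <- function(n, a, b, lo, hi) {
  qbeta(runif(n, pbeta(lo, a, b), pbeta(hi, a, b)), a, b)
}

#' Simulate a stromally confounded expression cohort
#'
#' See [cohort_sim_config()] for the generative model. Returns the log2
#' expression matrix together with a complete ground-truth record
#' (per-sample stromal fraction and fusion status, per-gene class label),
#' sufficient to score every downstream stage.
#'
#' @param config A [cohort_sim_config()].
#' @return List with elements `expr` (matrix, genes x samples, gene ids as
#'   rownames, sample ids as colnames), `truth` (list with data.frames
#'   `samples` and `genes`) and `signatures` (named list of the three
#'   stromal signature gene sets, as consumed by
#'   [compute_stromal_scores()]).
#' @export
simulate_cohort_expression <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  classes <- c("CAF", "Endo", "Leuco")
  sig_genes <- lapply(classes, function(cl)
    sprintf("%s_SIG_%02d", toupper(cl), seq_len(cfg$n_signature_genes)))
  names(sig_genes) <- classes
  bg_genes <- sprintf("BG_%03d", seq_len(cfg$n_background_genes))
  gene_ids <- c(unlist(sig_genes, use.names = FALSE), cfg$target_gene, bg_genes)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))

  f <- with_seed(derive_seed(cfg$seed, "stromal_fraction"),
                 rbeta(cfg$n_samples, cfg$stromal_beta[1], cfg$stromal_beta[2]))
  fused <- rep(FALSE, cfg$n_samples)
  if (cfg$n_fused > 0) {
    idx <- with_seed(derive_seed(cfg$seed, "fused_samples"),
                     sample.int(cfg$n_samples, cfg$n_fused))
    fused[idx] <- TRUE
    f[idx] <- with_seed(derive_seed(cfg$seed, "fused_fraction"),
                        rbeta_trunc(cfg$n_fused, cfg$stromal_beta[1],
                                    cfg$stromal_beta[2],
                                    cfg$fused_purity_range[1],
                                    cfg$fused_purity_range[2]))
  }

  n_sig_total <- length(classes) * cfg$n_signature_genes
  S <- with_seed(derive_seed(cfg$seed, "signature_coefficients"),
                 rlogunif(n_sig_total, 100, 2000))
  B <- with_seed(derive_seed(cfg$seed, "background_levels"),
                 rlogunif(cfg$n_background_genes, 10, 2000))

  sig_expr <- log2(1 + outer(S, f))
  target_expr <- log2(1 + cfg$stromal_coefficient_target * f +
                        cfg$epithelial_overexpr_level * as.numeric(fused))
  bg_expr <- matrix(rep(log2(1 + B), cfg$n_samples),
                    nrow = cfg$n_background_genes)
  expr <- rbind(sig_expr, matrix(target_expr, nrow = 1), bg_expr)
  if (cfg$noise_sd > 0) {
    noise <- with_seed(derive_seed(cfg$seed, "noise"),
                       matrix(rnorm(length(expr), 0, cfg$noise_sd),
                              nrow = nrow(expr)))
    expr <- expr + noise
  }
  dimnames(expr) <- list(gene_ids, sample_ids)

  truth <- list(
    samples = data.frame(sample = sample_ids, stromal_fraction = f,
                         fusion_status = fused),
    genes = data.frame(
      gene = gene_ids,
      class = c(rep(paste0(classes, "-signature"),
                    each = cfg$n_signature_genes),
                "target", rep("background", cfg$n_background_genes)))
  )
  list(expr = expr, truth = truth, signatures = sig_genes)
}
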