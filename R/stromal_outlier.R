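#' Per-sample signature score
#'
#' The stromal score of a sample is the arithmetic mean of the log2
#' expression of the signature genes resolvable in the matrix. Signature
#' genes missing from the matrix are reported, never silently dropped.
#'
#' @param expr Log2 expression matrix, genes x samples, gene ids as
#'   rownames.
#' @param genes Character vector of signature gene ids.
#' @return List with `score` (named numeric, one value per sample) and
#'   `unresolved` (signature genes absent from the matrix).
#' @export
compute_signature_score <- function(expr, genes) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  genes <- unique(genes)
  found <- intersect(genes, rownames(expr))
  if (length(found) == 0)
    stop("no signature gene resolvable in the expression matrix")
  score <- colMeans(expr[found, , drop = FALSE])
  list(score = score, unresolved = setdiff(genes, found))
}

#' Three stromal scores per sample
#'
#' @param expr Log2 expression matrix.
#' @param signatures Named list with elements `CAF`, `Endo`, `Leuco`
#'   (gene-id vectors), as produced by [simulate_cohort_expression()] or
#'   [read_signature_lists()].
#' @return data.frame with columns `sample`, `caf`, `endo`, `leuco`; the
#'   `unresolved` attribute lists unmatched genes per signature.
#' @export
compute_stromal_scores <- function(expr, signatures) {
  need <- c("CAF", "Endo", "Leuco")
  if (!all(need %in% names(signatures)))
    stop("signatures must contain CAF, Endo and Leuco gene lists")
  res <- lapply(signatures[need], function(g) compute_signature_score(expr, g))
  out <- data.frame(sample = colnames(expr),
                    caf = unname(res$CAF$score),
                    endo = unname(res$Endo$score),
                    leuco = unname(res$Leuco$score))
  attr(out, "unresolved") <- lapply(res, `[[`, "unresolved")
  out
}

#' Z-score standardization
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation. A
#' zero-variance input yields an all-zero vector flagged as degenerate
#' (attribute `degenerate`), never NaN.
#'
#' @param values Numeric vector, length >= 2.
#' @return Standardized numeric vector with a logical `degenerate`
#'   attribute.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("zscore needs at least 2 values")
  s <- sd(values)
  if (s == 0) {
    z <- rep(0, length(values))
    attr(z, "degenerate") <- TRUE
  } else {
    z <- (values - mean(values)) / s
    attr(z, "degenerate") <- FALSE
  }
  names(z) <- names(values)
  z
}

#' Pearson correlation with explicit degenerate-input handling
#'
#' @param x,y Numeric vectors of equal length >= 2, both non-constant.
#' @return The product-moment correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("pearson needs at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  cor(x, y, method = "pearson")
}

#' Stroma-corrected outlier analysis of a target gene
#'
#' For each sample, delta is the target log2 expression minus the CAF
#' score (subtraction on raw log2 values). Both the target expression
#' and delta are standardized cohort-wide; samples exceeding `z_expr`
#' (target Z) are expression outliers and samples exceeding `z_delta`
#' (delta Z) are stroma-corrected outliers — the fusion candidates. The
#' sign of delta assigns each sample to the positive or negative delta
#' group (delta exactly 0 goes to the negative group: candidacy requires
#' strictly positive delta). Setting `score_column` to `"endo"` or
#' `"leuco"` substitutes that stromal score for the CAF score.
#'
#' @param expr Log2 expression matrix.
#' @param target_gene Target gene id (must be a row of `expr`).
#' @param scores Score table from [compute_stromal_scores()], aligned to
#'   the samples of `expr`.
#' @param z_expr Target-expression Z threshold (default 2).
#' @param z_delta Delta Z threshold (default 2.5).
#' @param score_column Which stromal score delta subtracts.
#' @return An `outlier_report` data.frame with columns `sample`, `expr`,
#'   `expr_z`, `caf`, `endo`, `leuco`, `delta`, `delta_z`, `delta_sign`,
#'   `expr_outlier`, `delta_outlier`.
#' @export
delta_outlier_analysis <- function(expr, target_gene, scores,
                                   z_expr = 2.0, z_delta = 2.5,
                                   score_column = c("caf", "endo", "leuco")) {
  score_column <- match.arg(score_column)
  if (!target_gene %in% rownames(expr))
    stop("target gene ", target_gene, " not in the expression matrix")
  if (!identical(as.character(scores$sample), colnames(expr)))
    stop("sample mismatch between expression matrix and score table")
  tgt <- expr[target_gene, ]
  delta <- unname(tgt - scores[[score_column]])
  out <- data.frame(sample = colnames(expr), expr = unname(tgt),
                    expr_z = unname(as.numeric(zscore(tgt))),
                    caf = scores$caf, endo = scores$endo,
                    leuco = scores$leuco, delta = delta,
                    delta_z = as.numeric(zscore(delta)),
                    delta_sign = ifelse(delta > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out$expr_outlier <- out$expr_z > z_expr
  out$delta_outlier <- out$delta_z > z_delta
  attr(out, "thresholds") <- c(z_expr = z_expr, z_delta = z_delta)
  attr(out, "score_column") <- score_column
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' Expression-outlier candidates
#'
#' Samples whose target-expression Z-score exceeds the threshold the
#' report was computed with, sorted by descending Z.
#'
#' @param report An [delta_outlier_analysis()] report.
#' @return Character vector of sample ids.
#' @export
select_expression_outliers <- function(report) {
  sel <- report[report$expr_outlier, ]
  sel$sample[order(-sel$expr_z)]
}

#' Partition candidates by delta sign
#'
#' @param report An outlier report.
#' @param candidates Sample ids, subset of the report's samples.
#' @return List with `positive` and `negative` sample-id vectors
#'   (disjoint, exhaustive over the candidates; delta == 0 falls in the
#'   negative group).
#' @export
partition_by_delta_sign <- function(report, candidates) {
  unknown <- setdiff(candidates, report$sample)
  if (length(unknown) > 0)
    stop("unknown candidate sample(s): ", paste(unknown, collapse = ", "))
  sgn <- report$delta_sign[match(candidates, report$sample)]
  list(positive = candidates[sgn == "positive"],
       negative = candidates[sgn == "negative"])
}

#' Saturation search for additional low-stroma candidates
#'
#' Among samples that are neither excluded nor already expression
#' outliers, ranks by a two-key order — descending target-expression
#' stratum (deciles of the cohort target expression), then ascending CAF
#' score within stratum — so that for any expression level the samples
#' with the lowest stromal content come first. Returns the top `n`.
#'
#' @param report An outlier report.
#' @param n Number of samples to select.
#' @param exclude Sample ids never to return (e.g. already-screened
#'   candidates).
#' @return Character vector of up to `n` sample ids (fewer, with a
#'   warning, when the eligible pool is smaller).
#' @export
select_saturation_candidates <- function(report, n, exclude = character(0)) {
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(character(0))
  br <- unique(stats::quantile(report$expr, probs = 0:10 / 10))
  decile <- cut(report$expr, breaks = br, include.lowest = TRUE,
                labels = FALSE)
  pool <- !(report$sample %in% exclude) & !report$expr_outlier
  elig <- report[pool, ]
  elig_dec <- decile[pool]
  if (n > nrow(elig)) {
    warning("eligible pool (", nrow(elig), ") smaller than n = ", n)
    n <- nrow(elig)
  }
  ord <- order(-elig_dec, elig$caf)
  elig$sample[ord][seq_len(n)]
}

#' Fisher enrichment of fusion status across two sample groups
#'
#' Formalizes the exclusivity observation: a two-sided Fisher exact test
#' of the 2x2 group-by-status table, using the same exact-test engine as
#' the variant module ([fisher_exact_2x2()]).
#'
#' @param groups List of two character vectors of sample ids.
#' @param fusion_status Named logical vector (names = sample ids).
#' @return Two-sided p-value.
#' @export
enrichment_fisher <- function(groups, fusion_status) {
  if (length(groups) != 2) stop("groups must be a list of two sample sets")
  if (any(lengths(groups) == 0)) stop("empty group")
  st <- lapply(groups, function(g) {
    if (!all(g %in% names(fusion_status)))
      stop("fusion status missing for some samples")
    fusion_status[g]
  })
  fisher_exact_2x2(sum(st[[1]]), sum(!st[[1]]), sum(st[[2]]), sum(!st[[2]]))
}
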