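# Shared fixtures, built in code. Toy gene models are cached per session
# (deterministic under their seed) because several files use them.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_gene_models(seed = 3)
    cache
  }
})

toy_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy_fixture()
      cache <<- build_reference_index(toy$models, toy$genome)
    }
    cache
  }
})

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort_expression(cohort_sim_config(seed = 7))
    cache
  }
})

# A tiny two-exon minus-strand coding gene on a hand-written contig, for
# strand-convention checks. Transcript = revcomp(exon2) + revcomp(exon1)
# in genomic order terms; exons stored 5'->3'.
minus_strand_fixture <- function() {
  #          0         1         2         3
  #          0123456789012345678901234567890
  contig <- "TTTACGGATCCAATGCCGTAAGGCATCGATT"
  # genomic exons [3,12) and [19,28); minus strand so transcript order is
  # the downstream-in-genome exon first
  model <- gene_model("MG", "chrM", "-",
                      exons = rbind(c(19, 28), c(3, 12)),
                      cds = rbind(c(19, 28), c(3, 12)))
  list(genome = c(chrM = contig), model = model)
}

# Brute-force two-sided Fisher oracle: exact hypergeometric enumeration
# with binomial coefficients (no log-space, no dhyper).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  denom <- choose(m1 + m2, k)
  probs <- vapply(lo:hi, function(x)
    choose(m1, x) * choose(m2, k - x) / denom, numeric(1))
  obs <- probs[(lo:hi) == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}
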