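test_that("quality masking replaces sub-threshold bases with N", {
  s <- mask_low_quality("ACG", phred_to_char(c(19, 20, 21)))
  expect_equal(as.character(s), "NCG")  # strict inequality at the boundary
  expect_equal(attr(s, "n_masked"), 1L)

  hi <- mask_low_quality("ACGT", phred_to_char(rep(30, 4)))
  expect_equal(as.character(hi), "ACGT")
  lo <- mask_low_quality("ACGT", phred_to_char(rep(2, 4)))
  expect_equal(as.character(lo), "NNNN")
  expect_error(mask_low_quality("ACGT", "II"), "length")
})

test_that("fisher exact matches closed forms and stays in (0, 1]", {
  expect_identical(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 0, 1, 2), "negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")

  # symmetry under swapping samples, and ref/alt simultaneously
  set.seed(4)
  for (i in 1:50) {
    t <- rbinom(4, 30, 0.3)
    if (sum(t) == 0) next
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(fisher_exact_2x2(t[3], t[4], t[1], t[2]), p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t[2], t[1], t[4], t[3]), p,
                 tolerance = 1e-12)
  }

  # monotone toward the extreme at fixed margins
  p_seq <- vapply(0:5, function(a)
    fisher_exact_2x2(a, 10 - a, 10 - a, a), numeric(1))
  expect_true(all(diff(p_seq) >= -1e-12))
})

test_that("fisher exact equals the brute-force enumeration oracle", {
  # randomized sweep of small tables; the exhaustive sweep to margins 30
  # lives in the acceptance suite
  set.seed(11)
  for (i in 1:300) {
    t <- c(sample(0:12, 2, replace = TRUE), sample(0:12, 2, replace = TRUE))
    if (sum(t) == 0) next
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 fisher_oracle(t[1], t[2], t[3], t[4]), tolerance = 1e-9)
  }
  # and agrees with the standard library implementation
  for (t in list(c(6, 2, 0, 6), c(1, 9, 9, 1), c(3, 3, 3, 3))) {
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("indel classification keys on length difference mod 3", {
  expect_equal(classify_indel("AG", "A"),
               list(class = "deletion", length = 1L, frameshift = TRUE))
  expect_equal(classify_indel("AGTC", "A"),
               list(class = "deletion", length = 3L, frameshift = FALSE))
  expect_equal(classify_indel("A", "AGG"),
               list(class = "insertion", length = 2L, frameshift = TRUE))
  expect_equal(classify_indel("A", "G"),
               list(class = "SNV", length = 0L, frameshift = FALSE))
  expect_error(classify_indel("", "A"), "empty")
})

test_that("discordance calling applies AF, p-value and direction gates", {
  site <- function(ref_c, alt_c)
    data.frame(contig = "c", pos = c(100, 200, 300), ref = "AG", alt = "A",
               ref_count = ref_c, alt_count = alt_c)
  parental <- site(c(200, 200, 150), c(0, 0, 75))
  resistant <- site(c(100, 198, 152), c(100, 2, 76))
  calls <- call_discordant_variants(parental, resistant)
  # site 100: AF 0.5 gained, p tiny -> called
  # site 200: AF 0.01 < 0.015 -> never called regardless of p
  # site 300: identical proportions -> p = 1 -> not called
  expect_equal(calls$pos, 100)
  expect_equal(calls$af_resistant, 0.5)
  expect_equal(calls$class, "deletion")
  expect_true(calls$frameshift)
  expect_equal(calls$support, 100)

  # equal tables in both samples are never discordant
  same <- call_discordant_variants(parental, parental)
  expect_equal(nrow(same), 0)

  # depth gate: a shallow site is not tested
  p2 <- data.frame(contig = "c", pos = 1, ref = "A", alt = "T",
                   ref_count = 10, alt_count = 0)
  r2 <- data.frame(contig = "c", pos = 1, ref = "A", alt = "T",
                   ref_count = 2, alt_count = 8)
  expect_equal(nrow(call_discordant_variants(p2, r2, min_depth = 20)), 0)
  expect_equal(nrow(call_discordant_variants(p2, r2, min_depth = 10)), 1)

  expect_error(call_discordant_variants(parental, resistant[1:2, ]),
               "different sites")
})

test_that("protein effects follow the codon table and HGVS-like format", {
  genome <- c(chr1 = "ATGGGTAAACCCTTTGCA")
  mod <- gene_model("G1", "chr1", "+", cbind(0, 18), cds = cbind(0, 18))
  # 1-bp deletion in codon 2 (GGT, glycine)
  expect_equal(annotate_protein_effect(list(pos = 4, ref = "GG", alt = "G"),
                                       mod, genome), "p.G2fs")
  # exact 3-bp deletion of codon 2 -> in-frame
  expect_equal(annotate_protein_effect(list(pos = 3, ref = "GGGT", alt = "G"),
                                       mod, genome), "p.G2del")
  # missense and stop-gain SNVs
  expect_equal(annotate_protein_effect(list(pos = 10, ref = "C", alt = "A"),
                                       mod, genome), "p.P4T")
  expect_equal(annotate_protein_effect(list(pos = 7, ref = "A", alt = "T"),
                                       mod, genome), "p.K3*")
  # outside the CDS
  expect_equal(annotate_protein_effect(list(pos = 100, ref = "A", alt = "T"),
                                       mod, genome), "non-coding")
  expect_match(annotate_protein_effect(list(pos = 4, ref = "GG", alt = "G"),
                                       mod, genome), "^p\\.[A-Z*]\\d+fs$")
})

test_that("biallelic loss needs two distinct heterozygous LoF events", {
  mk <- function(pos, af, fs = TRUE)
    data.frame(contig = "c", pos = pos, ref = "AG", alt = "A",
               af_resistant = af, frameshift = fs,
               af_parental = 0, fisher_p = 1e-10, class = "deletion",
               support = 50)
  two <- rbind(mk(100, 0.45), mk(200, 0.52))
  res <- infer_biallelic_loss(two, "AXIN1L")
  expect_true(res$biallelic)
  expect_match(res$interpretation, "functionally homozygous")

  one_hom <- mk(100, 0.95)
  expect_false(infer_biallelic_loss(one_hom, "g")$biallelic)
  low <- rbind(mk(100, 0.45), mk(200, 0.05))
  expect_false(infer_biallelic_loss(low, "g")$biallelic)
  dup <- rbind(mk(100, 0.45), mk(100, 0.5))
  expect_false(infer_biallelic_loss(dup, "g")$biallelic)
  inframe <- rbind(mk(100, 0.45, fs = FALSE), mk(200, 0.5, fs = FALSE))
  expect_false(infer_biallelic_loss(inframe, "g")$biallelic)
})

test_that("planted-variant operating characteristics at small scale", {
  # resistant-specific AF 0.5 at depth 200: always called; AF 0.01: never
  hits <- vapply(1:20, function(s) {
    # the low-frequency variant drifts in both populations; the AF floor
    # (not the Fisher test) is what excludes it
    planted <- data.frame(pos = c(500, 900), ref = c("AG", "C"),
                          alt = c("A", "T"),
                          af_parental = c(0, 0.01),
                          af_resistant = c(0.5, 0.01),
                          depth_parental = c(200, 150),
                          depth_resistant = c(200, 150))
    spec <- pileup_sim_spec(n_sites = 10, planted_variants = planted,
                            seed = s)
    sim <- simulate_paired_pileup(spec)
    calls <- call_discordant_variants(sim$parental, sim$resistant)
    c(called_50 = 500 %in% calls$pos, called_1 = 900 %in% calls$pos)
  }, logical(2))
  expect_true(all(hits["called_50", ]))
  expect_false(any(hits["called_1", ]))
})
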