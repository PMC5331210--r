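test_that("reference index counts positions and rejects bad input", {
  toy <- toy_fixture()
  idx <- toy_index()
  expect_equal(idx$k, 21)
  expect_length(idx$ambiguous, 0)  # guaranteed by disjoint alphabets

  # single gene of length L indexes L - k + 1 positions
  g <- toy$models$RSPO3L
  one <- build_reference_index(list(RSPO3L = g), toy$genome, k = 21)
  txlen <- nchar(transcript_sequence(g, toy$genome))
  n_pos <- sum(vapply(ls(one$env), function(km) length(one$env[[km]]),
                      integer(1)))
  expect_equal(n_pos, txlen - 21 + 1)

  expect_error(build_reference_index(toy$models, toy$genome, k = 5),
               "at least 11")
  expect_error(build_reference_index(toy$models, toy$genome, k = 1e6),
               "shorter than k")
  dup <- list(a = toy$models$PTPRKL, b = toy$models$PTPRKL)
  expect_error(build_reference_index(dup, toy$genome), "duplicate")
})

test_that("anchor rule is sharp at 25 mapped nucleotides", {
  toy <- toy_fixture()
  idx <- toy_index()
  spec <- fusion_sim_spec(anchor_length_list = c(24, 25, 30, 45, 50, 51),
                          read_length = 75, seed = 11)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  aln <- align_reads(sim$reads, idx, min_anchor = 25)
  types <- vapply(aln, `[[`, character(1), "type")
  qualifying <- sim$truth$min_anchor >= 25
  expect_equal(unname(types == "split"), qualifying)
  expect_true(all(types[!qualifying] %in% c("linear", "unaligned")))
  # recovered anchors equal the planted ones (error-free)
  for (i in which(qualifying)) {
    a <- aln[[sim$truth$id[i]]]
    expect_equal(a$anchor5, sim$truth$anchor5[i])
    expect_equal(a$anchor3, sim$truth$anchor3[i])
    expect_true(a$gene5 == "PTPRKL" && a$gene3 == "RSPO3L")
  }
})

test_that("wild-type reads are linear, junk is unaligned", {
  toy <- toy_fixture()
  idx <- toy_index()
  spec <- fusion_sim_spec(n_junction_reads = 0, n_wildtype_reads = c(4, 4),
                          seed = 12)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  aln <- align_reads(sim$reads, idx)
  expect_true(all(vapply(aln, `[[`, character(1), "type") == "linear"))
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 75, replace = TRUE),
                collapse = "")
  expect_equal(align_read_split(junk, idx)$type, "unaligned")
})

test_that("e1->e2 and e13->e2 fusions are called with exact support", {
  toy <- toy_fixture()
  idx <- toy_index()
  for (bp5 in c(1, 13)) {
    spec <- fusion_sim_spec(breakpoint5 = bp5, breakpoint3 = 2,
                            anchor_length_list = rep(c(28, 35, 42), 4),
                            seed = bp5)
    sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
    calls <- call_fusions(align_reads(sim$reads, idx), toy$models)
    expect_equal(nrow(calls), 1)
    expect_equal(calls$gene5, "PTPRKL")
    expect_equal(calls$exon5, bp5)
    expect_equal(calls$gene3, "RSPO3L")
    expect_equal(calls$exon3, 2)
    expect_equal(calls$support, 12)  # every planted read qualifies
    expect_equal(calls$frame, "in-frame")
    expect_equal(calls$boundary, "at-exon-boundary")
  }
})

test_that("min_support filters weakly supported junctions", {
  toy <- toy_fixture()
  idx <- toy_index()
  spec <- fusion_sim_spec(anchor_length_list = 30, seed = 9)  # one read
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  aln <- align_reads(sim$reads, idx)
  expect_equal(nrow(call_fusions(aln, toy$models, min_support = 2)), 0)
  expect_equal(call_fusions(aln, toy$models, min_support = 1)$support, 1)
  expect_equal(nrow(call_fusions(list(), toy$models)), 0)
})

test_that("no false fusions from error-bearing background reads", {
  toy <- toy_fixture()
  idx <- toy_index()
  spec <- fusion_sim_spec(n_junction_reads = 0,
                          n_wildtype_reads = c(500, 500),
                          error_rate = 0.01, seed = 21)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  aln <- align_reads(sim$reads, idx)
  expect_equal(nrow(call_fusions(aln, toy$models, min_support = 1)), 0)
})

test_that("reverse-complementing every read leaves calls unchanged", {
  toy <- toy_fixture()
  idx <- toy_index()
  spec <- fusion_sim_spec(anchor_length_list = rep(c(26, 33, 40), 2),
                          n_wildtype_reads = c(5, 5), seed = 14)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  fwd <- call_fusions(align_reads(sim$reads, idx), toy$models)
  rc <- sim$reads
  rc$sequence <- reverse_complement(rc$sequence)
  rev <- call_fusions(align_reads(rc, idx), toy$models)
  expect_identical(fwd, rev)
})

test_that("reads with interior errors are still recovered as splits", {
  toy <- toy_fixture()
  idx <- toy_index()
  # plant one substitution well inside each segment of a 35/40 junction
  # read: seeding retains an exact 21-mer and extension tolerates it
  spec <- fusion_sim_spec(anchor_length_list = 35, seed = 2)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  read <- sim$reads$sequence[1]
  mutate <- function(s, i) {
    ch <- strsplit(s, "")[[1]]
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  noisy <- mutate(mutate(read, 5), 70)
  a <- align_read_split(noisy, idx)
  expect_equal(a$type, "split")
  expect_equal(a$anchor5, 35)
  expect_equal(a$mismatch5 + a$mismatch3, 2)
  # a third error in the same segment exceeds the per-segment budget
  worse <- mutate(mutate(noisy, 10), 15)
  expect_false(identical(align_read_split(worse, idx)$type, "split"))
})

test_that("frame annotation follows mod-3 arithmetic", {
  toy <- toy_fixture()
  m5 <- transcript_exon_map(toy$models$PTPRKL)
  m3 <- transcript_exon_map(toy$models$RSPO3L)
  bp5 <- m5$tend[1]; bp3 <- m3$tstart[2]
  expect_equal(annotate_frame("PTPRKL", bp5, "RSPO3L", bp3, toy$models),
               "in-frame")
  expect_equal(annotate_frame("PTPRKL", bp5 + 1, "RSPO3L", bp3, toy$models),
               "out-of-frame")
  expect_equal(annotate_frame("PTPRKL", m5$tend[13], "RSPO3L", bp3,
                              toy$models), "in-frame")
  # strip CDS -> non-coding
  nc <- toy$models
  nc$RSPO3L$cds <- NULL
  expect_equal(annotate_frame("PTPRKL", bp5, "RSPO3L", bp3, nc),
               "non-coding")
  expect_error(annotate_frame("PTPRKL", 1e9, "RSPO3L", bp3, toy$models),
               "outside transcript")
})

test_that("exon coverage counts segments on their own gene", {
  toy <- toy_fixture()
  idx <- toy_index()
  # fused-only simulation: no wild-type 3'-gene reads -> exon 1 bare
  spec <- fusion_sim_spec(anchor_length_list = rep(c(30, 40), 5),
                          n_wildtype_reads = c(10, 0), seed = 17)
  sim <- simulate_fusion_reads(spec, toy$models, toy$genome)
  aln <- align_reads(sim$reads, idx)
  cov3 <- exon_coverage(aln, toy$models$RSPO3L)
  expect_equal(cov3$n_reads[1], 0)
  expect_true(attr(cov3, "exon1_absent"))
  expect_gt(cov3$n_reads[2], 0)

  # adding wild-type 3'-gene reads populates exon 1
  spec2 <- fusion_sim_spec(anchor_length_list = rep(c(30, 40), 5),
                           n_wildtype_reads = c(0, 200), seed = 18)
  sim2 <- simulate_fusion_reads(spec2, toy$models, toy$genome)
  cov3b <- exon_coverage(align_reads(sim2$reads, idx), toy$models$RSPO3L)
  expect_gt(cov3b$n_reads[1], 0)
  expect_false(attr(cov3b, "exon1_absent"))

  empty <- exon_coverage(list(), toy$models$RSPO3L)
  expect_true(all(empty$n_reads == 0) && all(empty$n_bases == 0))
})
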