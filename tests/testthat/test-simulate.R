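test_that("genome generation is seed-deterministic with the stated GC", {
  g1 <- generate_genome(5000, gc = 0.5, seed = 9)
  g2 <- generate_genome(5000, gc = 0.5, seed = 9)
  expect_identical(g1, g2)
  big <- generate_genome(1e5, gc = 0.5, seed = 10)
  gcf <- mean(strsplit(big[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.5), 0.01)
  pure <- generate_genome(1000, gc = 1, seed = 11)
  expect_true(grepl("^[GC]+$", pure[[1]]))
})

test_that("planted precursors are disjoint and re-fold past the filter", {
  g <- generate_genome(40000, seed = 13)
  pl <- plant_hairpins(g, random_matures(8, seed = 14), seed = 15)
  tr <- pl$truth
  expect_equal(nrow(tr), 8L)
  ir <- IRanges::IRanges(tr$precursor_start + 1L, tr$precursor_end)
  expect_equal(sum(IRanges::countOverlaps(ir, ir)), 8L)   # only self-hits
  for (i in seq_len(nrow(tr))) {
    w <- extract_window(pl$genome, tr[i, ], flank = 120L)
    ft <- extract_features(fold(w$sequence), w$mature_start, w$mature_end)
    expect_gte(ft$mature_in_stem, 80)
    expect_true(criteria_pass(evaluate_criteria(ft)))
  }
})

test_that("simulated libraries reproduce their multinomial weights", {
  g <- generate_genome(40000, seed = 13)
  pl <- plant_hairpins(g, random_matures(8, seed = 14), seed = 15)
  sim <- simulate_reads(pl$truth, depth = 20000, noise_frac = 0,
                        shift_prob = 0, seed = 16)
  # determinism
  sim2 <- simulate_reads(pl$truth, depth = 20000, noise_frac = 0,
                         shift_prob = 0, seed = 16)
  expect_identical(sim$reads, sim2$reads)
  # with no noise every trimmed read is a planted mature sequence
  lib <- preprocess_fastq(sim$reads$AG, "AG")
  expect_true(all(lib$unique_reads$sequence %in% pl$truth$sequence))
  # chi-square goodness of fit against the generating weights
  cs <- suppressWarnings(
    chisq.test(sim$true_counts[, "AG"], p = sim$weights))
  expect_gt(cs$p.value, 0.01)
})

test_that("planted target sites carry their prescribed penalties", {
  cat <- make_catalog(2)
  ps <- plant_target_sites(8, cat, score_spec = c(0, 2, 5), seed = 17)
  for (i in seq_len(nrow(ps$truth))) {
    t <- ps$truth[i, ]
    site <- substr(ps$transcripts[[t$gene]], t$start + 1L, t$end)
    mir <- cat$sequence[cat$name == t$mirna]
    expect_equal(score_duplex(mir, site)$total, t$total)
  }
  expect_error(plant_target_sites(3, cat, score_spec = 1000, seed = 1),
               "unreachable")
})

test_that("matched qPCR panels recover their planted fold-changes", {
  fc <- c(m1 = 4, m2 = 1, m3 = 0.5)
  q <- simulate_qpcr(fc, seed = 18, noise_sd = 0.05)
  for (i in 1:3) {
    est <- relative_expression(
      as.numeric(q[i, 2:4]), as.numeric(q[i, 5:7]),
      as.numeric(q[i, 8:10]), as.numeric(q[i, 11:13]))
    expect_equal(log2(est), log2(fc[[i]]), tolerance = 0.3)
  }
})

test_that("a full study regenerates byte-identically from its seed", {
  s1 <- simulate_study(seed = 5, n_mirnas = 4, genome_len = 20000,
                       depth = 1000, transcript_count = 10)
  s2 <- simulate_study(seed = 5, n_mirnas = 4, genome_len = 20000,
                       depth = 1000, transcript_count = 10)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$qpcr, s2$qpcr)
})
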