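test_that("duplex scoring applies the penalty rules with 5' doubling", {
  set.seed(111)
  mir <- rand_seq(21)
  perfect <- revcomp(mir)
  expect_equal(score_duplex(mir, perfect)$total, 0)
  expect_error(score_duplex(mir, substr(perfect, 1, 20)), "equal")

  # an identical defect placed inside positions 2-13 scores exactly twice
  # its value outside
  for (i in 1:20) {
    mir <- rand_seq(21)
    site <- strsplit(revcomp(mir), "")[[1]]
    p_in <- sample(2:13, 1)
    p_out <- sample(c(1, 14:21), 1)
    mm_base <- function(mb) setdiff(c("A", "C", "G", "T"),
                                    c(chartr("ACGT", "TGCA", mb),
                                      if (mb == "G") "T",
                                      if (mb == "T") "G"))[1]
    m <- strsplit(mir, "")[[1]]
    s_in <- site; s_in[21 - p_in + 1] <- mm_base(m[p_in])
    s_out <- site; s_out[21 - p_out + 1] <- mm_base(m[p_out])
    t_in <- score_duplex(mir, paste(s_in, collapse = ""))$total
    t_out <- score_duplex(mir, paste(s_out, collapse = ""))$total
    expect_equal(t_in, 2); expect_equal(t_out, 1)
  }
})

test_that("defects are reported by miRNA position and kind", {
  mir <- "GAAAAAAAAGAAAGAAAAAAA"      # G at positions 1, 10, 14
  site <- strsplit(revcomp(mir), "")[[1]]
  site[21 - 1 + 1] <- "T"             # G:U facing position 1
  site[21 - 10 + 1] <- "T"            # G:U facing position 10 (doubled)
  d <- score_duplex(mir, paste(site, collapse = ""))
  expect_equal(d$total, 0.5 + 1.0)
  expect_equal(d$defects$position, c(1L, 10L))
  expect_equal(d$defects$kind, c("GU", "GU"))
})

test_that("adding a defect never lowers the total", {
  set.seed(113)
  for (i in 1:20) {
    mir <- rand_seq(21)
    site <- strsplit(revcomp(mir), "")[[1]]
    total_prev <- 0
    for (p in sample(21, 5)) {
      site[21 - p + 1] <- sample(c("A", "C", "G", "T"), 1)
      tot <- score_duplex(mir, paste(site, collapse = ""))$total
      expect_gte(tot, total_prev)
      total_prev <- tot
    }
  }
})

test_that("transcript scanning finds embedded sites and matches the
           exhaustive oracle", {
  set.seed(117)
  mir <- rand_seq(21)
  tx <- paste0(rand_seq(200), revcomp(mir), rand_seq(150))
  hits <- scan_transcript(mir, tx, cutoff = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 200)
  expect_equal(hits$total, 0)

  for (i in 1:8) {
    mir <- rand_seq(sample(19:22, 1))
    tx <- rand_seq(300)
    cutoff <- sample(c(4, 8, 12), 1)
    got <- scan_transcript(mir, tx, cutoff = cutoff)
    exp <- oracle_scan(mir, tx, cutoff)
    expect_equal(got$start, exp$start)
    expect_equal(got$total, exp$total)
  }
})

test_that("target prediction keeps the best site per gene and counts
           multiplicity", {
  set.seed(119)
  cat <- make_catalog(2)
  # gene1 carries sites for both miRNAs; gene2 none
  tx <- c(gene1 = paste0(rand_seq(50), revcomp(cat$sequence[1]),
                         rand_seq(30), revcomp(cat$sequence[2]),
                         rand_seq(50)),
          gene2 = rand_seq(200))
  tt <- predict_targets(cat, tx, cutoff = 0)
  expect_equal(nrow(tt), 2L)
  expect_equal(sort(unique(tt$gene)), "gene1")
  expect_equal(unique(tt$multiplicity), 2L)
  expect_equal(nrow(predict_targets(cat, character())), 0L)
})

test_that("planted sites of prescribed penalty are recovered exactly", {
  cat <- make_catalog(3)
  spec <- c(0, 0.5, 1, 2, 3.5, 4, 5)
  ps <- plant_target_sites(10, cat, score_spec = spec, seed = 7)
  tt <- predict_targets(cat, ps$transcripts, cutoff = 4)
  truth_le4 <- ps$truth[ps$truth$total <= 4, ]
  got <- merge(truth_le4, tt, by = c("mirna", "gene"))
  expect_equal(nrow(got), nrow(truth_le4))
  expect_equal(got$total.y, got$total.x)
  expect_equal(got$start.y, got$start.x)
  # above-cutoff plants are absent
  over <- ps$truth[ps$truth$total > 4, ]
  expect_false(any(paste(over$mirna, over$gene) %in%
                     paste(tt$mirna, tt$gene)))
})
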