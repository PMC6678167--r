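test_that("window extraction arithmetic and clipping", {
  set.seed(81)
  g <- c(chr1 = rand_seq(1000))
  hit <- data.frame(contig = "chr1", start = 200L, end = 221L,
                    strand = "+")
  w <- extract_window(g, hit, flank = 120L)
  expect_equal(c(w$window_start, w$window_end), c(80L, 341L))
  expect_equal(c(w$mature_start, w$mature_end), c(120L, 141L))
  expect_equal(substr(w$sequence, 121, 141),
               substr(g[[1]], 201, 221))
  # left clipping shifts the mature offset
  hit2 <- data.frame(contig = "chr1", start = 10L, end = 31L, strand = "+")
  w2 <- extract_window(g, hit2, flank = 120L)
  expect_equal(w2$window_start, 0L)
  expect_equal(w2$mature_start, 10L)
})

test_that("minus-strand windows round-trip the mature sequence", {
  set.seed(83)
  g <- c(chr1 = rand_seq(1000))
  read <- rand_seq(21)
  # plant the reverse complement on the forward strand
  pos <- 400L
  substr(g[[1]], pos + 1L, pos + 21L) <- revcomp(read)
  idx <- build_index(g)
  h <- map_read(read, idx, max_mm = 0L)
  h <- h[h$strand == "-", , drop = FALSE]
  expect_equal(nrow(h), 1L)
  w <- extract_window(g, h[1, ], flank = 50L)
  expect_equal(substr(w$sequence, w$mature_start + 1L, w$mature_end), read)
})

test_that("a perfect inverted repeat yields a clean full-stem feature set", {
  set.seed(87)
  arm <- rand_seq(20)
  hp <- paste0(arm, "ATCA", revcomp(arm))
  ft <- extract_features(fold(hp), 0L, 20L)
  expect_gte(ft$stem_bp, 20L)
  expect_equal(ft$mature_errors, 0L)
  expect_equal(ft$mature_in_stem, 100)
  expect_equal(ft$arm, "5p")
  expect_equal(ft$loop_len, 4L)
  expect_equal(ft$hairpin_len, 44L)
})

test_that("a one-sided 2-nt insertion in the mature arm is a biased bulge", {
  # hand-constructed structure: 8 pairs, 2-nt 5'-side bulge, 8 pairs, loop 4
  seq5 <- "GCGCGCGC"
  bulge <- "AA"
  seq5b <- "GGCCGGCC"
  loop <- "TTTT"
  s <- paste0(seq5, bulge, seq5b, loop, revcomp(seq5b), revcomp(seq5))
  db <- paste0(strrep("(", 8), "..", strrep("(", 8), "....",
               strrep(")", 8), strrep(")", 8))
  fr <- fold_result(s, db, -20)
  ft <- extract_features(fr, 0L, 18L)   # mature covers arm incl. the bulge
  expect_equal(ft$stem_bp, 16L)
  expect_equal(ft$mature_bulge_max, 2L)
  expect_equal(ft$mature_biased_bulges, 1L)
  expect_equal(ft$mature_biased_errors, 2L)
  expect_equal(ft$mature_errors, 2L)
  expect_equal(ft$mature_in_stem, 100)
})

test_that("a symmetric internal loop is not biased", {
  seq5 <- "GCGCGCGC"
  s <- paste0(seq5, "AA", seq5, "TTTT", revcomp(seq5), "AA", revcomp(seq5))
  db <- paste0(strrep("(", 8), "..", strrep("(", 8), "....",
               strrep(")", 8), "..", strrep(")", 8))
  ft <- extract_features(fold_result(s, db, -20), 0L, 18L)
  expect_equal(ft$mature_biased_bulges, 0L)
  expect_equal(ft$mature_bulge_max, 2L)
})

test_that("a mature span in the terminal loop scores zero percent in stem", {
  arm <- "GCGCGCGCGCGCGCGCGCGC"
  loop <- paste(rep("A", 22), collapse = "")
  s <- paste0(arm, loop, revcomp(arm))
  db <- paste0(strrep("(", 20), strrep(".", 22), strrep(")", 20))
  ft <- extract_features(fold_result(s, db, -30), 20L, 40L)
  expect_lt(ft$mature_in_stem, 80)
})

test_that("features ignore flanking sequence outside the selected unit", {
  set.seed(89)
  arm <- rand_seq(20)
  hp <- paste0(arm, "ATCAG", revcomp(arm))
  db <- paste0(strrep("(", 20), ".....", strrep(")", 20))
  bare <- extract_features(fold_result(hp, db, -25), 0L, 20L)
  pad <- 30L
  padded <- paste0(strrep("A", pad), hp, strrep("A", pad))
  dbp <- paste0(strrep(".", pad), db, strrep(".", pad))
  flanked <- extract_features(fold_result(padded, dbp, -25), pad, pad + 20L)
  for (f in c("stem_bp", "loop_len", "hairpin_len", "mature_bp",
              "mature_errors", "mature_in_stem")) {
    expect_equal(flanked[[f]], bare[[f]], info = f)
  }
})
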