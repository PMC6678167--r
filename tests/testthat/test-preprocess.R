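cfg <- preprocess_config(adapter = "TGGAATTCTCGGGTGCCAAGG")

test_that("adapter trimming returns the insert before the leftmost match", {
  ins <- "TGACAGAAGAGAGTGAGCAC"
  expect_equal(trim_adapter(paste0(ins, cfg$adapter), cfg), ins)
  # partial adapter at the read end, >= min overlap
  expect_equal(trim_adapter(paste0(ins, substr(cfg$adapter, 1, 7)), cfg),
               ins)
  # adapter dimer and adapter-free reads are dropped
  expect_true(is.na(trim_adapter(cfg$adapter, cfg)))
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGTACGTACGT", cfg)))
  # too-short terminal overlap does not count as a match
  expect_true(is.na(trim_adapter(paste0(ins, substr(cfg$adapter, 1, 4)),
                                 cfg)))
})

test_that("adapter trimming agrees with a brute-force all-positions scan", {
  set.seed(21)
  for (i in 1:300) {
    r <- rand_seq(sample(18:60, 1))
    if (runif(1) < 0.6) {
      cut <- sample(0:nchar(cfg$adapter), 1)
      pos <- sample(0:nchar(r), 1)
      r <- paste0(substr(r, 1, pos), substr(cfg$adapter, 1, cut))
    }
    expect_identical(trim_adapter(r, cfg),
                     oracle_trim(r, cfg$adapter, cfg$min_overlap),
                     info = r)
  }
})

test_that("read filtering rejects by length, N, complexity, contaminants", {
  expect_equal(filter_read("TGACAGAAGAGAGTGAGCAC", cfg), "keep")
  expect_equal(filter_read("TGACAGAAGAGAGTGAG", cfg), "length")   # 17 nt
  expect_equal(filter_read(strrep("A", 20), cfg), "low_complexity")
  expect_equal(filter_read("TGACAGAAGNGAGTGAGCAC", cfg), "N")
  ccfg <- preprocess_config(contaminants = "TGACAGAAGAGAGTGAGCAC")
  expect_equal(filter_read("TGACAGAAGAGAGTGAGCAC", ccfg), "contaminant")
  # one mismatch still matches the contaminant screen
  expect_equal(filter_read("TGACAGAAGAGAGTGAGCAA", ccfg), "contaminant")
  expect_equal(filter_read("TGACAGAAGAGCGTGAGCAA", ccfg), "keep")
})

test_that("collapsing counts duplicates with a deterministic order", {
  d <- collapse_unique(c("TTT", "AAA", "TTT", "CCC"))
  expect_equal(d$sequence, c("TTT", "AAA", "CCC"))   # count desc, then lex
  expect_equal(d$count, c(2L, 1L, 1L))
  expect_equal(nrow(collapse_unique(character())), 0L)
  # idempotence: collapsing a collapsed library is the identity
  again <- collapse_unique(rep(d$sequence, d$count))
  expect_equal(again, d)
})

test_that("read-fate accounting conserves the raw total", {
  set.seed(31)
  for (rep in 1:5) {
    reads <- c(
      paste0(vapply(1:50, function(i) rand_seq(sample(15:30, 1)), ""),
             cfg$adapter),
      vapply(1:10, function(i) rand_seq(40), ""),       # no adapter
      rep(cfg$adapter, 3))                              # dimers
    lib <- preprocess_fastq(reads, "AG", cfg)
    t <- lib$tallies
    expect_equal(t[["raw"]], length(reads))
    expect_equal(t[["valid"]],
                 t[["raw"]] - t[["adapter_length"]] - t[["junk"]])
    expect_equal(sum(lib$unique_reads$count), t[["valid"]])
    expect_true(all(nchar(lib$unique_reads$sequence) >= 18 &
                      nchar(lib$unique_reads$sequence) <= 25))
  }
})

test_that("library summary reports mapped percentages on the valid total", {
  set.seed(7)
  g <- generate_genome(2000, seed = 5)
  idx <- build_index(g)
  inserts <- vapply(sample(1:1900, 20), function(p) {
    substr(g[[1]], p, p + 19)
  }, "")
  lib <- preprocess_fastq(paste0(inserts, cfg$adapter), "AG", cfg)
  s <- summarize_library(lib, idx)
  expect_equal(s$value[s$metric == "Genome mapped (%)"], "100.00%")

  lib2 <- smrna_library(collapse_unique(
    vapply(1:10, function(i) rand_seq(25), "")), "CG")
  s2 <- summarize_library(lib2, idx)
  expect_equal(s2$value[s2$metric == "Genome mapped (%)"], "0.00%")
})
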