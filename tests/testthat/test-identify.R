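good_features <- function(...) {
  args <- list(stem_bp = 20L, stem_bulge_max = 2L, mfe = -30,
               loop_len = 8L, hairpin_len = 60L, mature_bp = 19L,
               mature_errors = 1L, mature_bulge_max = 1L,
               mature_biased_errors = 0L, mature_biased_bulges = 0L,
               mature_in_stem = 100)
  over <- list(...)
  args[names(over)] <- over
  do.call(hairpin_features, args)
}

test_that("the criterion filter passes comfortable margins and reports
           single failures by id", {
  rep0 <- evaluate_criteria(good_features())
  expect_true(criteria_pass(rep0))
  expect_equal(sum(!rep0$pass), 0L)

  r <- evaluate_criteria(good_features(mfe = -14))
  expect_false(criteria_pass(r))
  expect_equal(r$id[!r$pass], 3L)

  r <- evaluate_criteria(good_features(stem_bp = 15L))
  expect_equal(r$id[!r$pass], 1L)

  r <- evaluate_criteria(good_features(loop_len = 201L))
  expect_equal(r$id[!r$pass], 4L)
})

test_that("relaxing any threshold never turns a pass into a fail", {
  set.seed(91)
  lower_is_pass <- c("stem_bulge_max", "loop_len_max",
                     "mature_biased_errors_max", "mature_bulge_nt_max",
                     "mature_errors_max", "mature_biased_bulges_max",
                     "mfe_max")
  for (i in 1:30) {
    ft <- good_features(stem_bp = sample(10:25, 1),
                        mfe = -sample(5:40, 1),
                        mature_bp = sample(8:20, 1),
                        mature_errors = sample(0:6, 1),
                        mature_in_stem = sample(50:100, 1))
    base <- novel_criteria()
    passed <- criteria_pass(evaluate_criteria(ft, base))
    relaxed <- base
    nm <- sample(names(unclass(base)), 1)
    delta <- sample(1:5, 1)
    relaxed[[nm]] <- relaxed[[nm]] +
      if (nm %in% lower_is_pass) delta else -delta
    relaxed <- do.call(novel_criteria, unclass(relaxed))
    if (passed) {
      expect_true(criteria_pass(evaluate_criteria(ft, relaxed)), info = nm)
    }
  }
})

test_that("conserved annotation confirms genome-backed hits and flags
           sequence-only matches", {
  set.seed(93)
  cat <- make_catalog(3)
  g <- generate_genome(20000, seed = 17)
  planted <- plant_hairpins(g, setNames(cat$sequence[1], "m1"), seed = 19)
  idx <- build_index(planted$genome)
  lib <- smrna_library(collapse_unique(
    rep(cat$sequence[1:2], c(5L, 2L))))
  ann <- annotate_conserved(lib, cat, idx)
  expect_equal(nrow(ann), 2L)
  r1 <- ann[ann$sequence == cat$sequence[1], ]
  expect_true(r1$confirmed)
  expect_equal(r1$start, planted$truth$start)
  expect_match(r1$name, "^csl-miR901")
  r2 <- ann[ann$sequence == cat$sequence[2], ]   # not in the genome
  expect_false(r2$confirmed)
})

test_that("novel discovery recovers planted hairpins and names them by
           abundance", {
  set.seed(97)
  g <- generate_genome(30000, seed = 23)
  mats <- random_matures(4, seed = 29)
  planted <- plant_hairpins(g, mats, seed = 31)
  idx <- build_index(planted$genome)
  counts <- c(40L, 30L, 20L, 10L)
  lib <- smrna_library(collapse_unique(rep(planted$truth$sequence, counts)))
  nov <- discover_novel(lib, idx)
  expect_equal(nrow(nov), 4L)
  expect_equal(nov$name, paste0("csl-nmiR", 1:4))
  expect_equal(nov$sequence, planted$truth$sequence)  # count order
  # each reported locus lies inside its planted precursor (either arm of
  # the hairpin is a faithful recovery)
  expect_true(all(nov$start >= planted$truth$precursor_start &
                    nov$end <= planted$truth$precursor_end))
  expect_equal(nov$class, rep("novel", 4))
})

test_that("discovery reports nothing on a shuffled genome", {
  set.seed(101)
  g <- generate_genome(30000, seed = 23)
  mats <- random_matures(4, seed = 29)
  planted <- plant_hairpins(g, mats, seed = 31)
  shuffled <- paste(sample(strsplit(planted$genome[[1]], "")[[1]]),
                    collapse = "")
  idx <- build_index(c(chr1 = shuffled))
  lib <- smrna_library(collapse_unique(rep(planted$truth$sequence, 10L)))
  expect_equal(nrow(discover_novel(lib, idx)), 0L)
})

test_that("family parsing follows the reference nomenclature", {
  expect_equal(assign_family("csl-miR166a-5p-1"), "miR166")
  expect_equal(assign_family("csl-MIR7700-5p"), "miR7700")
  expect_equal(assign_family("csl-MiR9558-5p"), "miR9558")
  expect_equal(assign_family("csl-nmiR3", class = "novel"), "csl-nmiR3")
  expect_error(assign_family("csl-weird"), "cannot parse")
})

test_that("catalog statistics reproduce the bundled catalog structure", {
  st <- family_stats(c169_catalog())
  expect_equal(st$n_families, 73L)
  expect_equal(st$largest_family, "miR166")
  expect_equal(st$largest_size, 11L)
  expect_equal(sum(st$members == 1L), 58L)
  expect_equal(st$singleton_percent, 79.45)
  expect_equal(st$n_conserved, 118L)
  expect_equal(st$n_novel, 6L)
  expect_equal(sum(st$length_histogram), 124L)
})
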