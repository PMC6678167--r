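test_that("index construction validates its input", {
  expect_error(build_index(character()), "empty genome")
  expect_warning(build_index(c(chr1 = strrep("N", 100))), "only N")
  idx <- build_index(c(chr1 = rand_seq(100)))
  expect_error(map_read("ACGTACGT", idx), "shorter than")
})

test_that("exact and one-mismatch hits are found at planted loci", {
  set.seed(41)
  g <- c(chr1 = rand_seq(3000))
  read <- substr(g[[1]], 501, 521)
  idx <- build_index(g)
  h <- map_read(read, idx, max_mm = 0L)
  expect_true(any(h$start == 500 & h$end == 521 & h$strand == "+" &
                    h$mm == 0))
  # central substitution: found only when a mismatch is allowed
  sub <- read
  mid <- 11L
  substr(sub, mid, mid) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read, mid, mid))[1]
  expect_true(any(map_read(sub, idx, max_mm = 1L)$start == 500))
  expect_false(any(map_read(sub, idx, max_mm = 0L)$start == 500))
})

test_that("genome mapping equals the exhaustive Hamming scan", {
  set.seed(43)
  g <- c(c1 = rand_seq(4000), c2 = rand_seq(2000))
  idx <- build_index(g)
  for (i in 1:25) {
    read <- if (i %% 3 == 0) {
      s <- sample(1:3980, 1)
      r <- substr(g[[1]], s, s + 19)              # planted (maybe mutated)
      if (i %% 2 == 0) {
        p <- sample(1:20, 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    } else rand_seq(20)
    for (mm in 0:1) {
      expect_equal(map_read(read, idx, max_mm = mm),
                   oracle_map(read, g, mm), info = paste(read, mm))
    }
  }
})

test_that("mapping is strand-symmetric", {
  set.seed(47)
  g <- c(chr1 = rand_seq(3000))
  idx <- build_index(g)
  for (i in 1:10) {
    s <- sample(1:2970, 1)
    read <- substr(g[[1]], s, s + 20)
    fwd <- map_read(read, idx, max_mm = 1L)
    rev <- map_read(revcomp(read), idx, max_mm = 1L)
    expect_equal(fwd$start, rev$start)
    expect_equal(fwd$strand, chartr("+-", "-+", rev$strand))
  }
})

test_that("reference matching honors end shifts and mismatches", {
  cat <- make_catalog(3)
  ref <- cat$sequence[1]
  h <- map_to_mature_refs(ref, cat, max_shift = 2, max_mm = 1)
  expect_equal(h$name[1], cat$name[1])
  expect_equal(unlist(h[1, c("shift5", "shift3", "mm")]),
               c(shift5 = 0, shift3 = 0, mm = 0))
  # reference minus its last 2 nt: 3' trim of 2, no mismatches
  h2 <- map_to_mature_refs(substr(ref, 1, nchar(ref) - 2), cat,
                           max_shift = 2, max_mm = 0)
  expect_equal(h2$shift3[h2$name == cat$name[1]], 2)
  # beyond the shift budget: no hit
  h3 <- map_to_mature_refs(substr(ref, 1, nchar(ref) - 3), cat,
                           max_shift = 2, max_mm = 0)
  expect_false(cat$name[1] %in% h3$name)
})

test_that("reference matching equals exhaustive shift-mismatch search", {
  set.seed(53)
  cat <- make_catalog(6)
  oracle_match <- function(q, ref, max_shift, max_mm) {
    qq <- strsplit(q, "")[[1]]
    rr <- strsplit(ref, "")[[1]]
    best <- NULL
    for (d5 in -max_shift:max_shift) {
      d3 <- length(rr) - d5 - length(qq)
      if (abs(d3) > max_shift) next
      ov <- seq_len(length(rr))
      ov <- ov[ov > max(d5, 0) & ov <= length(rr) - max(d3, 0)]
      if (!length(ov)) next
      mm <- sum(rr[ov] != qq[ov - d5])
      if (mm > max_mm) next
      sc <- c(mm, abs(d5) + abs(d3))
      if (is.null(best) || mm < best[1] ||
          (mm == best[1] && sc[2] < best[2])) best <- sc
    }
    best
  }
  for (i in 1:40) {
    q <- if (i %% 2 == 0) {
      ref <- sample(cat$sequence, 1)
      n <- nchar(ref)
      t5 <- sample(0:3, 1); t3 <- sample(0:3, 1)
      r <- substr(ref, 1 + t5, n - t3)
      if (runif(1) < 0.5 && nchar(r) > 2) {
        p <- sample(nchar(r), 1)
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r
    } else rand_seq(21)
    got <- map_to_mature_refs(q, cat, max_shift = 3, max_mm = 1)
    for (j in seq_len(nrow(cat))) {
      exp <- oracle_match(q, cat$sequence[j], 3, 1)
      row <- got[got$name == cat$name[j], ]
      if (is.null(exp)) {
        expect_equal(nrow(row), 0L, info = q)
      } else {
        expect_equal(nrow(row), 1L, info = q)
        expect_equal(row$mm, exp[1], info = q)
        expect_equal(abs(row$shift5) + abs(row$shift3), exp[2], info = q)
      }
    }
  }
})
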