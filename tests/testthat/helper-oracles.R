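## Independent reference implementations used as oracles. These are written
## as direct brute-force scans/enumerations and deliberately share no code
## with the package internals.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

## all-positions Hamming scan of a read against a genome, both strands
oracle_map <- function(read, genome, max_mm) {
  hits <- list()
  rc <- oracle_revcomp(read)
  for (contig in names(genome)) {
    g <- strsplit(genome[[contig]], "")[[1]]
    for (strand in c("+", "-")) {
      pat <- strsplit(if (strand == "+") read else rc, "")[[1]]
      w <- length(pat)
      if (length(g) < w) next
      for (s in 0:(length(g) - w)) {
        mm <- sum(g[(s + 1):(s + w)] != pat)
        if (mm <= max_mm) {
          hits[[length(hits) + 1L]] <- data.frame(
            contig = contig, start = s, end = s + w, strand = strand,
            mm = mm)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mm = integer()))
  }
  d <- do.call(rbind, hits)
  d <- d[order(d$contig, d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## leftmost adapter occurrence by scanning every position explicitly
oracle_trim <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  la <- nchar(adapter)
  for (p in seq_len(n)) {
    l <- min(la, n - p + 1L)
    if (l < min(la, max(min_overlap, 1L))) next
    if (l < la && l < min_overlap) next
    if (substr(read, p, p + l - 1L) == substr(adapter, 1L, l)) {
      if (p == 1L) return(NA_character_)        # dimer
      return(substr(read, 1L, p - 1L))
    }
  }
  NA_character_
}

## penalty arithmetic written independently (explicit pair-by-pair rules)
oracle_duplex_total <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    t <- s[L - i + 1L]           # transcript base facing miRNA position i
    wc <- (m[i] == "A" && t == "T") || (m[i] == "T" && t == "A") ||
      (m[i] == "G" && t == "C") || (m[i] == "C" && t == "G")
    gu <- (m[i] == "G" && t == "T") || (m[i] == "T" && t == "G")
    p <- if (wc) 0 else if (gu) 0.5 else 1
    if (i >= 2 && i <= 13) p <- 2 * p
    total <- total + p
  }
  total
}

## every window of a transcript scored with the oracle arithmetic
oracle_scan <- function(mirna, transcript, cutoff) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  out <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      tot <- oracle_duplex_total(mirna, substr(transcript, s + 1L, s + L))
      if (tot <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(start = s, total = tot)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), total = numeric()))
  d <- do.call(rbind, out)
  d[order(d$total, d$start), , drop = FALSE]
}

## maximum base pairs by memoized enumeration over all structures
## (minimum loop 3, AU/GC/GU), decomposed differently from the package DP
oracle_max_pairs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  comp <- function(x, y) paste0(x, y) %in% c("AT", "TA", "GC", "CG",
                                             "GT", "TG")
  memo <- new.env()
  f <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- f(i + 1L, j)
    for (k in seq(i + 4L, j)) {
      if (comp(b[i], b[k])) {
        v <- 1L + f(i + 1L, k - 1L) + (if (k < j) f(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  f(1L, length(b))
}

## hypergeometric upper tail by complete enumeration of draws
oracle_hyper_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2L, function(d) sum(d %in% marked) >= k))
}

## a tiny catalog of random miRNAs for construction-based tests
make_catalog <- function(n = 4L, len = 21L, class = "conserved") {
  mirseed::mirna_catalog(data.frame(
    family = paste0("miR", 900 + seq_len(n)),
    name = paste0("osa-miR", 900 + seq_len(n)),
    sequence = vapply(seq_len(n), function(i) rand_seq(len), ""),
    class = class))
}
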