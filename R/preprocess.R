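## Raw FASTQ -> collapsed unique-read library with a per-stage accounting of
## read fates (the library-summary table schema).

#' Preprocessing configuration
#'
#' @param adapter 3' adapter sequence (default: Illumina TruSeq small-RNA
#'   3' adapter).
#' @param min_len,max_len retained insert length bounds in nt.
#' @param low_complexity_frac reject inserts whose most frequent single
#'   nucleotide exceeds this fraction.
#' @param min_overlap minimum exact adapter overlap (nt) for a trailing
#'   partial adapter match.
#' @param contaminants character vector of contaminant sequences (rRNA,
#'   tRNA, sn/snoRNA, repeats); inserts matching one exactly or with one
#'   mismatch are rejected. Default empty.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                              min_len = 18L, max_len = 25L,
                              low_complexity_frac = 0.8,
                              min_overlap = 6L,
                              contaminants = character()) {
  adapter <- norm_seq(adapter)
  stopifnot(nchar(adapter) >= min_overlap, min_len <= max_len,
            min_len >= 1L, low_complexity_frac > 0, low_complexity_frac <= 1)
  structure(list(adapter = adapter, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 low_complexity_frac = low_complexity_frac,
                 min_overlap = as.integer(min_overlap),
                 contaminants = norm_seq(contaminants)),
            class = "preprocess_config")
}

#' Trim the 3' adapter from reads
#'
#' Returns the insert preceding the left-most adapter occurrence. A match is
#' either the full adapter anywhere in the read, or a prefix of the adapter
#' (at least `min_overlap` nt) flush with the read end. Reads with no
#' adapter occurrence, and adapter dimers (match at position 1), yield `NA`.
#'
#' @param reads character vector of raw read sequences.
#' @param config a [preprocess_config()].
#' @return character vector of inserts, `NA` where the read is dropped.
#' @export
trim_adapter <- function(reads, config = preprocess_config()) {
  reads <- norm_seq(reads)
  ad <- config$adapter
  la <- nchar(ad)
  pos <- as.integer(regexpr(ad, reads, fixed = TRUE))
  ## partial adapter at the read end (longest, i.e. leftmost, wins); a full
  ## match is always left of any tail partial, so only fill the misses
  miss <- pos < 0L
  if (any(miss) && la > config$min_overlap) {
    for (l in seq(la - 1L, config$min_overlap)) {
      if (!any(miss)) break
      hit <- miss & endsWith(reads, substr(ad, 1L, l))
      pos[hit] <- nchar(reads[hit]) - l + 1L
      miss <- miss & !hit
    }
  }
  out <- rep(NA_character_, length(reads))
  keep <- pos > 1L
  out[keep] <- substr(reads[keep], 1L, pos[keep] - 1L)
  out[pos == 1L] <- ""   # adapter dimer: empty insert
  out[out == ""] <- NA_character_
  out
}

#' Filter trimmed inserts
#'
#' Applies the length window, an `N` screen, a low-complexity screen
#' (dominant single-nucleotide fraction) and an optional contaminant screen
#' (exact or one-mismatch match to a user-supplied set).
#'
#' @param seqs character vector of trimmed inserts.
#' @param config a [preprocess_config()].
#' @return character vector of per-read fates: `"keep"`, `"length"`, `"N"`,
#'   `"low_complexity"` or `"contaminant"`.
#' @export
filter_read <- function(seqs, config = preprocess_config()) {
  seqs <- norm_seq(seqs)
  n <- nchar(seqs)
  out <- rep("keep", length(seqs))
  out[n < config$min_len | n > config$max_len] <- "length"
  todo <- out == "keep"
  if (any(todo)) {
    out[todo & grepl("N", seqs, fixed = TRUE)] <- "N"
  }
  todo <- out == "keep"
  if (any(todo)) {
    s2 <- seqs[todo]
    counts <- matrix(unlist(lapply(.base_alphabet, function(b) {
      nchar(s2) - nchar(gsub(b, "", s2, fixed = TRUE))
    })), nrow = length(s2))
    frac <- apply(counts, 1L, max) / n[todo]
    out[todo][frac >= config$low_complexity_frac] <- "low_complexity"
  }
  if (length(config$contaminants)) {
    todo <- which(out == "keep")
    if (length(todo)) {
      hit <- vapply(seqs[todo], function(s) {
        any(nchar(config$contaminants) == nchar(s) &
              .hamming(s, config$contaminants) <= 1L)
      }, logical(1L), USE.NAMES = FALSE)
      out[todo][hit] <- "contaminant"
    }
  }
  out
}

## vectorised Hamming distance of s against equal-length candidates
## (unequal lengths -> Inf)
.hamming <- function(s, cands) {
  n <- nchar(s)
  d <- rep(Inf, length(cands))
  eq <- nchar(cands) == n
  if (!any(eq)) return(d)
  a <- strsplit(s, "")[[1]]
  d[eq] <- vapply(strsplit(cands[eq], ""),
                  function(b) sum(a != b), numeric(1L))
  d
}

#' Collapse reads to a unique-sequence table
#'
#' @param reads character vector of retained inserts.
#' @return data.frame with columns `sequence` and `count`, ordered by count
#'   descending then sequence lexicographically; `sum(count)` equals
#'   `length(reads)`.
#' @export
collapse_unique <- function(reads) {
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(), count = integer()))
  }
  tab <- table(reads)
  d <- data.frame(sequence = names(tab), count = as.integer(tab))
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Preprocess a small-RNA FASTQ into a collapsed library
#'
#' Runs adapter trimming, the junk filters and read collapsing, keeping the
#' per-stage tallies (raw, adapter/length-removed, junk-removed, valid).
#'
#' @param fastq path to the raw FASTQ (optionally gzipped), or a character
#'   vector of raw read sequences.
#' @param condition condition label (e.g. `"AG"` or `"CG"`).
#' @param config a [preprocess_config()].
#' @return a `smrna_library`: list with `condition`, `unique_reads`
#'   (sequence/count data.frame) and `tallies`.
#' @export
preprocess_fastq <- function(fastq, condition = "NA",
                             config = preprocess_config()) {
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq(fastq)$sequence
  } else {
    norm_seq(fastq)
  }
  raw <- length(reads)
  inserts <- trim_adapter(reads, config)
  ## accounting: adapter-or-length removal is one tally (library-summary
  ## schema), remaining junk screens are the other
  fate <- rep("adapter", raw)
  has_insert <- !is.na(inserts)
  fate[has_insert] <- filter_read(inserts[has_insert], config)
  fate[fate == "adapter"] <- "adapter_length"
  fate[fate == "length"] <- "adapter_length"
  fate[fate %in% c("N", "low_complexity", "contaminant")] <- "junk"
  kept <- inserts[fate == "keep"]
  smrna_library(collapse_unique(kept), condition = condition,
                tallies = c(raw = raw,
                            adapter_length = sum(fate == "adapter_length"),
                            junk = sum(fate == "junk"),
                            valid = length(kept)))
}

#' Construct a small-RNA library object
#'
#' @param unique_reads data.frame with `sequence` and `count`.
#' @param condition condition label.
#' @param tallies named numeric vector with at least `raw`,
#'   `adapter_length`, `junk`, `valid`.
#' @return a `smrna_library` list.
#' @export
smrna_library <- function(unique_reads, condition = "NA", tallies = NULL) {
  if (is.null(tallies)) {
    v <- sum(unique_reads$count)
    tallies <- c(raw = v, adapter_length = 0, junk = 0, valid = v)
  }
  stopifnot(sum(unique_reads$count) == tallies[["valid"]],
            tallies[["valid"]] ==
              tallies[["raw"]] - tallies[["adapter_length"]] -
              tallies[["junk"]])
  structure(list(condition = condition, unique_reads = unique_reads,
                 tallies = tallies),
            class = "smrna_library")
}

#' @export
print.smrna_library <- function(x, ...) {
  t <- x$tallies
  cat("small-RNA library [", x$condition, "]: ",
      t[["valid"]], " valid reads, ", nrow(x$unique_reads),
      " unique sequences\n", sep = "")
  cat("  raw ", t[["raw"]], " | adapter/length -", t[["adapter_length"]],
      " | junk -", t[["junk"]], "\n", sep = "")
  invisible(x)
}

#' Library summary in the sequencing-report schema
#'
#' Emits the per-library accounting (raw reads, adapter/length filtered,
#' junk reads, valid reads, genome-mapped reads and percentage, unique
#' reads), mirroring a standard small-RNA sequencing summary table.
#'
#' @param lib a `smrna_library`.
#' @param genome_index a [build_index()] genome index (or `NULL` to skip
#'   the mapping rows).
#' @param max_mm mismatches allowed when deciding "genome mapped".
#' @return data.frame with columns `metric` and `value`; percentages are
#'   formatted with two decimals.
#' @export
summarize_library <- function(lib, genome_index = NULL, max_mm = 0L) {
  t <- lib$tallies
  rows <- data.frame(
    metric = c("Raw data", "3' adaptor sequence & length filter",
               "Junk reads", "Valid reads"),
    value = as.character(c(t[["raw"]], t[["adapter_length"]],
                           t[["junk"]], t[["valid"]]))
  )
  if (!is.null(genome_index)) {
    ur <- lib$unique_reads
    mapped <- vapply(ur$sequence, function(s) {
      nrow(map_read(s, genome_index, max_mm = max_mm)) > 0L
    }, logical(1L), USE.NAMES = FALSE)
    gm <- sum(ur$count[mapped])
    pct <- if (t[["valid"]] > 0) 100 * gm / t[["valid"]] else 0
    rows <- rbind(rows, data.frame(
      metric = c("Genome mapped", "Genome mapped (%)", "Unique reads"),
      value = c(as.character(gm), sprintf("%.2f%%", pct),
                as.character(nrow(ur)))
    ))
  }
  rows
}
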