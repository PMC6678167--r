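## Exact and one-mismatch mapping of short reads to a desk-scale genome and
## to a reference mature-miRNA catalog. Hamming matching is exact (no
## heuristic seeds are exposed): per-contig matching delegates to
## Biostrings, which is complete for the <=1-mismatch regime.

#' Build a genome index
#'
#' Stores contigs and their reverse complements for strand-symmetric short
#' read matching. `k` is the minimum query length accepted by
#' [map_read()].
#'
#' @param genome named character vector of contig sequences, a data.frame
#'   as returned by [read_fasta()], or a path to a genome FASTA.
#' @param k minimum seed length (default 12).
#' @return a `genome_index` list.
#' @export
build_index <- function(genome, k = 12L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.data.frame(genome)) {
    genome <- setNames(genome$sequence, genome$id)
  }
  genome <- norm_seq(genome)
  if (length(genome) == 0L || all(!nzchar(genome))) {
    stop("empty genome", call. = FALSE)
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("contig", seq_along(genome))
  }
  if (all(grepl("^N*$", genome))) {
    warning("genome contains only N bases; index is empty")
  }
  fwd <- Biostrings::DNAStringSet(genome)
  structure(list(contigs = fwd,
                 rev = Biostrings::reverseComplement(fwd),
                 lengths = setNames(nchar(genome), names(genome)),
                 k = as.integer(k)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome index: ", length(x$contigs), " contig(s), ",
      sum(x$lengths), " nt total, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Map a read to the genome
#'
#' Finds every locus on either strand matching the read with at most
#' `max_mm` substitutions. Reverse-strand hits are reported in forward
#' coordinates with a strand flag.
#'
#' @param seq read sequence (18-25 nt typical; must be at least `k` nt).
#' @param index a [build_index()] object.
#' @param max_mm 0 or 1 allowed mismatches.
#' @return data.frame with columns `contig`, `start` (0-based), `end`
#'   (half-open), `strand`, `mm`, sorted by (contig, start, strand).
#' @export
map_read <- function(seq, index, max_mm = 1L) {
  seq <- norm_seq(seq)
  stopifnot(max_mm %in% c(0L, 1L))
  if (nchar(seq) < index$k) {
    stop("query (", nchar(seq), " nt) shorter than index seed k = ",
         index$k, call. = FALSE)
  }
  pat <- Biostrings::DNAString(seq)
  w <- nchar(seq)
  hits <- list()
  for (ci in seq_along(index$contigs)) {
    cname <- names(index$lengths)[ci]
    clen <- index$lengths[[ci]]
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") index$contigs[[ci]] else index$rev[[ci]]
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m) - 1L
      mm <- vapply(seq_along(m), function(i) {
        Biostrings::neditAt(pat, subj, at = st[i] + 1L)
      }, integer(1L))
      keep <- mm <= max_mm   # matchPattern can return N-padded edge hits
      if (!any(keep)) next
      st <- st[keep]; mm <- mm[keep]
      if (strand == "-") st <- clen - (st + w)
      hits[[length(hits) + 1L]] <- data.frame(
        contig = cname, start = st, end = st + w, strand = strand, mm = mm)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mm = integer()))
  }
  d <- do.call(rbind, hits)
  d <- d[order(d$contig, d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Match a read against reference mature miRNAs
#'
#' A query matches a reference when it can be obtained from the reference
#' by trimming or extending at most `max_shift` nt at each end plus at most
#' `max_mm` substitutions in the overlapping region. Shifts are positive
#' when the query is trimmed relative to the reference and negative when it
#' extends beyond it.
#'
#' @param seq query sequence.
#' @param catalog a `mirna_catalog` (or data.frame with `name`,
#'   `sequence`).
#' @param max_shift maximum end shift per end in nt (default 3).
#' @param max_mm 0 or 1 substitutions in the overlap.
#' @return data.frame with columns `name`, `shift5`, `shift3`, `mm`, sorted
#'   best-first by (mm, |shift5|+|shift3|, name); zero rows when no
#'   reference is reachable.
#' @export
map_to_mature_refs <- function(seq, catalog, max_shift = 3L, max_mm = 1L) {
  seq <- norm_seq(seq)
  stopifnot(max_shift >= 0L, max_mm %in% c(0L, 1L))
  q <- strsplit(seq, "")[[1]]
  lq <- length(q)
  res <- list()
  for (i in seq_len(nrow(catalog))) {
    ref <- catalog$sequence[i]
    r <- strsplit(ref, "")[[1]]
    lr <- length(r)
    best <- NULL
    for (d5 in seq(-max_shift, max_shift)) {
      d3 <- lr - d5 - lq
      if (abs(d3) > max_shift) next
      ## overlap in reference coordinates: [max(d5,0)+1, lr-max(d3,0)]
      ov_r <- seq.int(max(d5, 0L) + 1L, lr - max(d3, 0L))
      if (length(ov_r) == 0L) next
      ov_q <- ov_r - d5
      mm <- sum(r[ov_r] != q[ov_q])
      if (mm > max_mm) next
      cand <- c(mm = mm, shift5 = d5, shift3 = d3)
      if (is.null(best) ||
          mm < best[["mm"]] ||
          (mm == best[["mm"]] &&
           abs(d5) + abs(d3) < abs(best[["shift5"]]) + abs(best[["shift3"]])))
        best <- cand
    }
    if (!is.null(best)) {
      res[[length(res) + 1L]] <- data.frame(
        name = catalog$name[i], shift5 = best[["shift5"]],
        shift3 = best[["shift3"]], mm = best[["mm"]])
    }
  }
  if (length(res) == 0L) {
    return(data.frame(name = character(), shift5 = integer(),
                      shift3 = integer(), mm = integer()))
  }
  d <- do.call(rbind, res)
  d <- d[order(d$mm, abs(d$shift5) + abs(d$shift3), d$name), , drop = FALSE]
  rownames(d) <- NULL
  d
}
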