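## Candidate precursor windows and the structural features consumed by the
## eleven-criterion novel-miRNA filter.

#' Extract a flanked precursor window around a genome hit
#'
#' Takes the genomic window `[start - flank, end + flank)` on the hit
#' strand (clipped at contig ends) and re-expresses the mature read span in
#' window coordinates. Minus-strand windows are reverse-complemented so the
#' mature sequence reads 5'->3'.
#'
#' @param genome named character vector of contigs (or [read_fasta()]
#'   data.frame, or a `genome_index`).
#' @param hit one-row data.frame (or list) with `contig`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param flank flanking length in nt on each side (default 120).
#' @return list with `sequence`, `mature_start`/`mature_end` (0-based
#'   half-open within the window), `contig`, `window_start`, `window_end`
#'   (genomic, forward coordinates) and `strand`.
#' @export
extract_window <- function(genome, hit, flank = 120L) {
  if (inherits(genome, "genome_index")) {
    genome <- setNames(as.character(genome$contigs), names(genome$lengths))
  }
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  contig_seq <- genome[[hit$contig]]
  clen <- nchar(contig_seq)
  ws <- max(0L, hit$start - flank)
  we <- min(clen, hit$end + flank)
  win <- substr(contig_seq, ws + 1L, we)
  if (hit$strand == "+") {
    ms <- hit$start - ws
    me <- hit$end - ws
  } else {
    win <- revcomp(win)
    ms <- we - hit$end
    me <- we - hit$start
  }
  list(sequence = win, mature_start = ms, mature_end = me,
       contig = hit$contig, window_start = ws, window_end = we,
       strand = hit$strand)
}

## decompose a pair table into stem-loop units: maximal unbranched chains
## of nested pairs (bulges and internal loops allowed). A chain continues
## inward while its pair encloses exactly one top-level pair; it ends at a
## hairpin loop or at a multiloop branch. Everything enclosed by the
## innermost chain pair — including any sub-hairpins — counts as the
## terminal loop of the unit.
.stem_loops <- function(pt) {
  n <- length(pt)
  opens <- which(pt > seq_len(n))
  if (length(opens) == 0L) return(list())
  top_level_inner <- function(a, b) {
    res <- integer(0)
    i <- a + 1L
    while (i < b) {
      if (pt[i] > i) { res <- c(res, i); i <- pt[i] + 1L }
      else i <- i + 1L
    }
    res
  }
  cont <- rep(NA_integer_, n)
  for (a in opens) {
    tl <- top_level_inner(a, pt[a])
    if (length(tl) == 1L) cont[a] <- tl
  }
  starts <- setdiff(opens, cont[!is.na(cont)])
  lapply(starts, function(a0) {
    chain <- a0
    a <- a0
    while (!is.na(cont[a])) {
      a <- cont[a]
      chain <- c(chain, a)
    }
    list(pairs = cbind(chain, pt[chain]),
         span = c(a0, pt[a0]),
         loop = c(a, pt[a]))
  })
}

#' Extract hairpin features for the criterion filter
#'
#' Selects the stem-loop of the folded window that maximizes overlap with
#' the mature span and measures: stem base pairs, the largest stem bulge,
#' the energy estimate, terminal loop length, total hairpin length, and the
#' mature-region statistics (base pairs, errors = unpaired mature stem
#' positions, largest bulge touching the mature region, biased one-sided
#' errors/bulges, and the percentage of the mature read lying in the stem).
#' A "biased" bulge is one-sided: its unpaired nucleotides face zero
#' unpaired nucleotides on the opposing arm.
#'
#' @param fold a [fold_result()].
#' @param mature_start,mature_end mature span within the folded window,
#'   0-based half-open.
#' @return a `hairpin_features` list (all fields finite; a mature span
#'   outside every stem-loop yields `mature_in_stem = 0`).
#' @export
extract_features <- function(fold, mature_start, mature_end) {
  pt <- pair_table(fold$structure)
  M <- seq.int(mature_start + 1L, mature_end)   # 1-based mature positions
  sls <- .stem_loops(pt)
  zero <- hairpin_features(
    stem_bp = 0L, stem_bulge_max = 0L, mfe = fold$energy, loop_len = 0L,
    hairpin_len = 0L, mature_bp = 0L, mature_errors = 0L,
    mature_bulge_max = 0L, mature_biased_errors = 0L,
    mature_biased_bulges = 0L, mature_in_stem = 0,
    arm = "none", span = c(0L, 0L))
  if (length(sls) == 0L) return(zero)
  ## overlap with the stem arms (not the enclosed loop): a mature span
  ## sitting in a unit's multiloop belongs to an inner unit, not to it
  overlap <- vapply(sls, function(sl) {
    arms <- c(seq.int(sl$span[1], sl$loop[1]),
              seq.int(sl$loop[2], sl$span[2]))
    length(intersect(M, arms))
  }, integer(1L))
  if (max(overlap) == 0L) return(zero)
  sl <- sls[[which.max(overlap)]]
  A <- sl$span[1]; B <- sl$span[2]
  i0 <- sl$loop[1]; j0 <- sl$loop[2]
  pairs <- sl$pairs   # outer -> inner rows
  ## bulges between consecutive stem pairs
  bulges <- list()
  if (nrow(pairs) > 1L) {
    for (t in seq_len(nrow(pairs) - 1L)) {
      ao <- pairs[t, 1]; bo <- pairs[t, 2]
      ai <- pairs[t + 1L, 1]; bi <- pairs[t + 1L, 2]
      gap5 <- ai - ao - 1L
      gap3 <- bo - bi - 1L
      if (gap5 > 0L) {
        bulges[[length(bulges) + 1L]] <-
          list(size = gap5, pos = seq.int(ao + 1L, ai - 1L),
               biased = gap3 == 0L)
      }
      if (gap3 > 0L) {
        bulges[[length(bulges) + 1L]] <-
          list(size = gap3, pos = seq.int(bi + 1L, bo - 1L),
               biased = gap5 == 0L)
      }
    }
  }
  stem_pos <- c(seq.int(A, i0), seq.int(j0, B))   # arms incl. bulges
  pair_pos <- c(pairs[, 1], pairs[, 2])
  m_stem <- intersect(M, stem_pos)
  m_bulges <- Filter(function(bg) length(intersect(bg$pos, M)) > 0L, bulges)
  biased_m <- Filter(function(bg) bg$biased, m_bulges)
  hairpin_features(
    stem_bp = nrow(pairs),
    stem_bulge_max = if (length(bulges))
      max(vapply(bulges, `[[`, 0L, "size")) else 0L,
    mfe = fold$energy,
    loop_len = j0 - i0 - 1L,
    hairpin_len = B - A + 1L,
    mature_bp = length(intersect(M, pair_pos)),
    mature_errors = length(setdiff(m_stem, pair_pos)),
    mature_bulge_max = if (length(m_bulges))
      max(vapply(m_bulges, `[[`, 0L, "size")) else 0L,
    mature_biased_errors = if (length(biased_m))
      max(vapply(biased_m, function(bg) length(intersect(bg$pos, M)), 0L))
      else 0L,
    mature_biased_bulges = length(biased_m),
    mature_in_stem = 100 * length(m_stem) / length(M),
    arm = if (mean(M) <= i0) "5p" else if (mean(M) >= j0) "3p" else "loop",
    span = c(A, B))
}

#' Construct a hairpin feature set
#'
#' @param stem_bp stem base-pair count.
#' @param stem_bulge_max largest stem bulge (nt).
#' @param mfe energy estimate (kcal/mol).
#' @param loop_len terminal loop length (nt).
#' @param hairpin_len total hairpin length: 5' arm + loop + 3' arm (nt).
#' @param mature_bp base pairs in the mature region.
#' @param mature_errors unpaired mature positions in the stem.
#' @param mature_bulge_max largest bulge (nt) touching the mature region.
#' @param mature_biased_errors most mature nucleotides in any one-sided
#'   bulge.
#' @param mature_biased_bulges count of one-sided bulges touching the
#'   mature region.
#' @param mature_in_stem percent of the mature read inside the stem.
#' @param arm `"5p"`, `"3p"`, `"loop"` or `"none"`.
#' @param span stem-loop span (1-based inclusive) in the window.
#' @return a `hairpin_features` list.
#' @export
hairpin_features <- function(stem_bp, stem_bulge_max, mfe, loop_len,
                             hairpin_len, mature_bp, mature_errors,
                             mature_bulge_max, mature_biased_errors,
                             mature_biased_bulges, mature_in_stem,
                             arm = "none", span = c(0L, 0L)) {
  x <- list(stem_bp = stem_bp, stem_bulge_max = stem_bulge_max, mfe = mfe,
            loop_len = loop_len, hairpin_len = hairpin_len,
            mature_bp = mature_bp, mature_errors = mature_errors,
            mature_bulge_max = mature_bulge_max,
            mature_biased_errors = mature_biased_errors,
            mature_biased_bulges = mature_biased_bulges,
            mature_in_stem = mature_in_stem, arm = arm, span = span)
  num <- unlist(x[setdiff(names(x), c("arm", "span"))])
  stopifnot(all(is.finite(num)), mature_in_stem >= 0, mature_in_stem <= 100)
  structure(x, class = "hairpin_features")
}

#' @export
print.hairpin_features <- function(x, ...) {
  cat("hairpin features: stem ", x$stem_bp, " bp, bulge<=", x$stem_bulge_max,
      " nt, E=", sprintf("%.2f", x$mfe), " kcal/mol, loop ", x$loop_len,
      " nt, length ", x$hairpin_len, " nt\n",
      "  mature (", x$arm, "): ", x$mature_bp, " bp, ", x$mature_errors,
      " errors, ", sprintf("%.1f", x$mature_in_stem), "% in stem\n",
      sep = "")
  invisible(x)
}
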