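## miRNA target prediction with the complementarity penalty system:
## mismatch 1 point, G:U wobble 0.5 points, both doubled at miRNA
## positions 2-13 from the 5' end; a site totalling 4 points or less is a
## potential target site.

## penalty lookup for (miRNA base, transcript base): 0 Watson-Crick,
## 0.5 G:U wobble, 1 mismatch
.penalty_matrix <- local({
  m <- matrix(1, 4L, 4L, dimnames = list(.base_alphabet, .base_alphabet))
  m["A", "T"] <- 0; m["T", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "T"] <- 0.5; m["T", "G"] <- 0.5   # miRNA G : target U and U : G
  m
})

#' Score a miRNA/target-site duplex
#'
#' The site is the transcript segment written 5'->3'; it is scored against
#' the miRNA in reverse-complement orientation, so miRNA position `i`
#' (1-based from the miRNA 5' end) faces site position `L - i + 1`.
#' Watson-Crick pairs score 0, G:U wobbles 0.5, mismatches 1, with the
#' penalty doubled at miRNA positions 2-13.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3'.
#' @param site_seq transcript segment of equal length, 5'->3'.
#' @return a `duplex_score`: list with `total`, and `defects` (data.frame
#'   `position` from the miRNA 5' end, `kind` `"GU"` or `"MM"`,
#'   `penalty`).
#' @export
#' @examples
#' score_duplex("ACGTACGTACGTACGTACGTA",
#'              revcomp("ACGTACGTACGTACGTACGTA"))$total  # 0
score_duplex <- function(mirna_seq, site_seq) {
  mirna_seq <- norm_seq(mirna_seq)
  site_seq <- norm_seq(site_seq)
  if (nchar(mirna_seq) != nchar(site_seq)) {
    stop("ungapped scoring requires equal miRNA and site lengths",
         call. = FALSE)
  }
  m <- strsplit(mirna_seq, "")[[1]]
  t5 <- rev(strsplit(site_seq, "")[[1]])  # site base facing miRNA pos i
  L <- length(m)
  pen <- vapply(seq_len(L), function(i) {
    if (m[i] %in% .base_alphabet && t5[i] %in% .base_alphabet) {
      .penalty_matrix[m[i], t5[i]]
    } else 1
  }, numeric(1L))
  doubled <- seq_len(L) >= 2L & seq_len(L) <= 13L
  pen <- pen * ifelse(doubled, 2, 1)
  idx <- which(pen > 0)
  kind <- ifelse(.is_gu(m[idx], t5[idx]), "GU", "MM")
  structure(list(
    total = sum(pen),
    defects = data.frame(position = idx, kind = kind, penalty = pen[idx])
  ), class = "duplex_score")
}

.is_gu <- function(m, t) (m == "G" & t == "T") | (m == "T" & t == "G")

#' @export
print.duplex_score <- function(x, ...) {
  cat("duplex penalty total:", x$total, "\n")
  if (nrow(x$defects)) {
    cat(" ", paste0(x$defects$position, ":", x$defects$kind,
                    collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scan a transcript for miRNA target sites
#'
#' Scores every window of miRNA length along the transcript (sense strand
#' only) and returns the sites at or below the penalty cutoff, sorted by
#' (total ascending, position ascending). Overlapping sites are allowed.
#'
#' @param mirna_seq mature miRNA sequence 5'->3'.
#' @param transcript transcript sequence (sense-strand mRNA).
#' @param cutoff penalty cutoff (default 4).
#' @return data.frame with `start`, `end` (0-based half-open site span on
#'   the transcript), `total` and `defects` (compact string such as
#'   `"5:MM,9:GU"`).
#' @export
scan_transcript <- function(mirna_seq, transcript, cutoff = 4) {
  mirna_seq <- norm_seq(mirna_seq)
  transcript <- norm_seq(transcript)
  L <- nchar(mirna_seq)
  n <- nchar(transcript)
  empty <- data.frame(start = integer(), end = integer(),
                      total = numeric(), defects = character())
  if (n < L) return(empty)
  m <- strsplit(mirna_seq, "")[[1]]
  tb <- strsplit(transcript, "")[[1]]
  mi <- match(m, .base_alphabet)
  ti <- match(tb, .base_alphabet)
  dbl <- ifelse(seq_len(L) >= 2L & seq_len(L) <= 13L, 2, 1)
  starts <- 0:(n - L)   # 0-based
  ## miRNA position i faces transcript position start + L - i (0-based)
  totals <- numeric(length(starts))
  penm <- matrix(0, nrow = L, ncol = length(starts))
  for (i in seq_len(L)) {
    tpos <- starts + L - i + 1L   # 1-based transcript index
    p <- ifelse(is.na(mi[i]) | is.na(ti[tpos]), 1,
                .penalty_matrix[cbind(mi[i], ti[tpos])])
    penm[i, ] <- p * dbl[i]
  }
  totals <- colSums(penm)
  keep <- which(totals <= cutoff)
  if (length(keep) == 0L) return(empty)
  res <- data.frame(
    start = starts[keep], end = starts[keep] + L, total = totals[keep],
    defects = vapply(keep, function(k) {
      idx <- which(penm[, k] > 0)
      if (!length(idx)) return("")
      gu <- .is_gu(m[idx], tb[starts[k] + L - idx + 1L])
      paste0(idx, ":", ifelse(gu, "GU", "MM"), collapse = ",")
    }, "")
  )
  res <- res[order(res$total, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict target genes for a miRNA catalog
#'
#' Scans every transcript with every catalog miRNA and keeps the best site
#' (lowest penalty, then leftmost) per (miRNA, gene) pair at or below the
#' cutoff. The `multiplicity` column counts how many distinct miRNAs
#' target each gene.
#'
#' @param catalog a `mirna_catalog` (or data.frame with `name`,
#'   `sequence`).
#' @param transcriptome named character vector of transcript sequences, a
#'   [read_fasta()] data.frame, or a FASTA path.
#' @param cutoff penalty cutoff (default 4).
#' @return data.frame with `mirna`, `gene`, `start`, `end`, `total`,
#'   `defects`, `multiplicity`.
#' @export
predict_targets <- function(catalog, transcriptome, cutoff = 4) {
  if (is.character(transcriptome) && length(transcriptome) == 1L &&
      file.exists(transcriptome)) {
    transcriptome <- read_fasta(transcriptome)
  }
  if (is.data.frame(transcriptome)) {
    transcriptome <- setNames(transcriptome$sequence, transcriptome$id)
  }
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    for (g in names(transcriptome)) {
      sites <- scan_transcript(catalog$sequence[i], transcriptome[[g]],
                               cutoff = cutoff)
      if (nrow(sites) == 0L) next
      best <- sites[1L, ]   # already sorted: lowest total, then leftmost
      out[[length(out) + 1L]] <- data.frame(
        mirna = catalog$name[i], gene = g, start = best$start,
        end = best$end, total = best$total, defects = best$defects)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      start = integer(), end = integer(),
                      total = numeric(), defects = character(),
                      multiplicity = integer()))
  }
  d <- do.call(rbind, out)
  mult <- table(d$gene)
  d$multiplicity <- as.integer(mult[d$gene])
  rownames(d) <- NULL
  d
}
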