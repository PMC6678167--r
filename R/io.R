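## Readers/writers for the external formats the pipeline touches.
## Parsing is delegated to Biostrings; a light pre-validation pass supplies
## line-numbered format errors for the malformed inputs Biostrings would
## reject opaquely (or silently accept).

#' Read a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalized to DNA `T`; record
#' order is preserved.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a data.frame with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  .validate_fasta(path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  data.frame(
    id = vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L),
    sequence = norm_seq(as.character(ss)),
    row.names = NULL
  )
}

.validate_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(NULL))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) {
    stop("FASTA format error at line 1: expected '>' header", call. = FALSE)
  }
  bad_hdr <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad_hdr)) {
    stop("FASTA format error at line ", bad_hdr[1L],
         ": header has no identifier", call. = FALSE)
  }
  ## a header immediately followed by a header (or EOF) has no sequence
  nxt <- c(hdr[-1L], TRUE)
  empty <- which(hdr & nxt)
  if (length(empty)) {
    stop("FASTA format error at line ", empty[1L],
         ": record has an empty sequence", call. = FALSE)
  }
  seq_lines <- which(!hdr & nzchar(lines))
  bad <- seq_lines[grepl("[^A-Za-z*.-]", lines[seq_lines])]
  if (length(bad)) {
    stop("FASTA format error at line ", bad[1L],
         ": illegal sequence character", call. = FALSE)
  }
  invisible(NULL)
}

#' Write sequences to a FASTA file
#'
#' @param ids character vector of record identifiers.
#' @param sequences character vector of sequences (same length as `ids`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  ss <- Biostrings::BStringSet(setNames(as.character(sequences), ids))
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line records; gzip input is decompressed transparently. Qualities
#' are returned but not otherwise used by the pipeline.
#'
#' @param path path to a FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `sequence` (normalized to upper-case
#'   DNA) and `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error: truncated record near line ", length(lines),
         call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character()))
  }
  at <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(at, "@")) || any(!startsWith(pl, "+"))) {
    bad <- which(!startsWith(at, "@") | !startsWith(pl, "+"))[1L]
    stop("FASTQ format error at record ", bad, ": malformed header lines",
         call. = FALSE)
  }
  if (any(nchar(sq) != nchar(qu))) {
    bad <- which(nchar(sq) != nchar(qu))[1L]
    stop("FASTQ format error at record ", bad,
         ": sequence and quality lengths differ", call. = FALSE)
  }
  data.frame(
    id = sub("^@", "", vapply(strsplit(at, "[ \t]"), `[`, "", 1L)),
    sequence = norm_seq(sq),
    quality = qu
  )
}

#' Write reads to a FASTQ file
#'
#' @param ids,sequences,qualities parallel character vectors; `qualities`
#'   defaults to constant `"I"` per base.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, sequences, qualities = NULL, path) {
  if (is.null(qualities)) {
    qualities <- vapply(nchar(sequences),
                        function(n) strrep("I", n), "")
  }
  stopifnot(length(ids) == length(sequences),
            length(qualities) == length(sequences),
            all(nchar(sequences) == nchar(qualities)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qualities), con)
  invisible(path)
}

#' Parse a mature-miRNA catalog
#'
#' Reads a tab-separated catalog with columns `family`, `name`, `sequence`
#' and `class` (`conserved` or `novel`), such as the bundled C-169 catalog
#' (see [c169_catalog()]). Sequences are normalized to the DNA alphabet.
#'
#' @param path path to the TSV catalog.
#' @return a `mirna_catalog`: a data.frame with the four columns above.
#' @export
parse_mirna_catalog <- function(path) {
  stopifnot(file.exists(path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    warning("empty miRNA catalog: ", path)
    d <- data.frame(family = character(), name = character(),
                    sequence = character(), class = character())
    return(mirna_catalog(d))
  }
  need <- c("family", "name", "sequence", "class")
  if (!all(need %in% names(d))) {
    stop("catalog is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  mirna_catalog(d[, need])
}

#' Construct a miRNA catalog object
#'
#' @param records data.frame with columns `family`, `name`, `sequence`,
#'   `class`.
#' @return the validated data.frame with class `mirna_catalog`.
#' @export
mirna_catalog <- function(records) {
  records$sequence <- norm_seq(records$sequence)
  if (anyDuplicated(records$name)) {
    stop("duplicate miRNA name(s): ",
         paste(unique(records$name[duplicated(records$name)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", records$sequence) & nzchar(records$sequence)
  if (nrow(records) && any(bad | !nzchar(records$sequence))) {
    stop("illegal character or empty sequence in catalog record(s): ",
         paste(head(records$name[bad | !nzchar(records$sequence)], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(records) && !all(records$class %in% c("conserved", "novel"))) {
    stop("catalog class must be 'conserved' or 'novel'", call. = FALSE)
  }
  structure(records, class = c("mirna_catalog", "data.frame"))
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat("miRNA catalog: ", nrow(x), " records (",
      sum(x$class == "conserved"), " conserved, ",
      sum(x$class == "novel"), " novel)\n", sep = "")
  if (nrow(x)) print.data.frame(head(x, 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more\n")
  invisible(x)
}

#' The bundled C-169 miRNA catalog
#'
#' The 124 mature miRNAs (118 conserved, 6 novel) identified in
#' *Coccomyxa subellipsoidea* C-169, with family labels.
#'
#' @return a `mirna_catalog` of 124 records.
#' @export
#' @examples
#' cat124 <- c169_catalog()
#' table(cat124$class)
c169_catalog <- function() {
  parse_mirna_catalog(system.file("extdata", "c169_mirna_catalog.tsv",
                                  package = "mirseed", mustWork = TRUE))
}

#' Read a gene-to-term annotation table
#'
#' Expects a two-column TSV `gene<TAB>term;term;...`; an optional
#' two-column label TSV `term<TAB>label` supplies display labels. Terms
#' without a label entry get a placeholder label equal to the term id.
#'
#' @param path annotation TSV.
#' @param label_path optional term-label TSV.
#' @param namespace annotation namespace tag (`"GO-like"` or
#'   `"pathway-like"`).
#' @return a list with `genes` (named list gene -> character vector of
#'   terms), `labels` (named character vector term -> label) and
#'   `namespace`.
#' @export
read_annotation <- function(path, label_path = NULL,
                            namespace = c("GO-like", "pathway-like")) {
  namespace <- match.arg(namespace)
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("gene", "terms"))
  if (nrow(d) == 0L) stop("empty annotation: ", path, call. = FALSE)
  genes <- strsplit(d$terms, ";", fixed = TRUE)
  names(genes) <- d$gene
  terms <- unique(unlist(genes))
  labels <- setNames(terms, terms)
  if (!is.null(label_path)) {
    lab <- read.delim(label_path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("term", "label"))
    labels[lab$term] <- lab$label
  }
  list(genes = genes, labels = labels, namespace = namespace)
}

#' Write precursor loci as GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive with the strand column set.
#'
#' @param records data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"` or `"-"`), `id`, and optionally `type`
#'   (default `miRNA_primary_transcript`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(records, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(records) || nrow(records) == 0L) return(invisible(path))
  if (!all(records$strand %in% c("+", "-"))) {
    stop("record without a strand cannot be written to GFF3", call. = FALSE)
  }
  type <- if ("type" %in% names(records)) records$type else
    "miRNA_primary_transcript"
  writeLines(paste(records$contig, "mirseed", type,
                   records$start + 1L, records$end, ".", records$strand, ".",
                   paste0("ID=", records$id), sep = "\t"), con)
  invisible(path)
}
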