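## Conserved-miRNA annotation, novel-miRNA discovery through the
## eleven-criterion structural filter, family assignment and catalog
## statistics.

#' The eleven structural criteria for novel miRNA precursors
#'
#' Default thresholds: (1) stem base pairs >= 16; (2) nucleotides in one
#' stem bulge <= 12; (3) folding free energy <= -15 kcal/mol; (4) hairpin
#' loop length <= 200 nt; (5) hairpin length (both stem arms plus terminal
#' loop) >= 50 nt; (6) biased errors in one bulge in the mature region
#' <= 2; (7) nucleotides in one bulge in the mature region <= 4; (8) base
#' pairs in the mature region >= 12; (9) errors in the mature region <= 4;
#' (10) biased bulges in the mature region <= 2; (11) percent of the mature
#' read in the stem >= 80.
#'
#' @param stem_bp_min,stem_bulge_max,mfe_max,loop_len_max,hairpin_len_min
#'   thresholds for criteria 1-5.
#' @param mature_biased_errors_max,mature_bulge_nt_max,mature_bp_min
#'   thresholds for criteria 6-8.
#' @param mature_errors_max,mature_biased_bulges_max,mature_in_stem_min
#'   thresholds for criteria 9-11.
#' @return a `novel_criteria` list.
#' @export
novel_criteria <- function(stem_bp_min = 16, stem_bulge_max = 12,
                           mfe_max = -15, loop_len_max = 200,
                           hairpin_len_min = 50,
                           mature_biased_errors_max = 2,
                           mature_bulge_nt_max = 4, mature_bp_min = 12,
                           mature_errors_max = 4,
                           mature_biased_bulges_max = 2,
                           mature_in_stem_min = 80) {
  x <- list(stem_bp_min = stem_bp_min, stem_bulge_max = stem_bulge_max,
            mfe_max = mfe_max, loop_len_max = loop_len_max,
            hairpin_len_min = hairpin_len_min,
            mature_biased_errors_max = mature_biased_errors_max,
            mature_bulge_nt_max = mature_bulge_nt_max,
            mature_bp_min = mature_bp_min,
            mature_errors_max = mature_errors_max,
            mature_biased_bulges_max = mature_biased_bulges_max,
            mature_in_stem_min = mature_in_stem_min)
  stopifnot(all(vapply(x, is.numeric, TRUE)), mfe_max <= 0,
            mature_in_stem_min >= 0, mature_in_stem_min <= 100)
  structure(x, class = "novel_criteria")
}

#' Apply the eleven-criterion filter to hairpin features
#'
#' @param features a [hairpin_features()] set.
#' @param criteria a [novel_criteria()] threshold set.
#' @return a `criterion_report`: data.frame with one row per criterion
#'   (`id`, `measure`, `value`, `threshold`, `pass`) and attribute
#'   `overall` (logical AND of all eleven).
#' @export
evaluate_criteria <- function(features, criteria = novel_criteria()) {
  f <- features
  cr <- criteria
  rows <- data.frame(
    id = 1:11,
    measure = c("stem_bp", "stem_bulge_max", "mfe", "loop_len",
                "hairpin_len", "mature_biased_errors", "mature_bulge_max",
                "mature_bp", "mature_errors", "mature_biased_bulges",
                "mature_in_stem"),
    value = c(f$stem_bp, f$stem_bulge_max, f$mfe, f$loop_len, f$hairpin_len,
              f$mature_biased_errors, f$mature_bulge_max, f$mature_bp,
              f$mature_errors, f$mature_biased_bulges, f$mature_in_stem),
    threshold = c(cr$stem_bp_min, cr$stem_bulge_max, cr$mfe_max,
                  cr$loop_len_max, cr$hairpin_len_min,
                  cr$mature_biased_errors_max, cr$mature_bulge_nt_max,
                  cr$mature_bp_min, cr$mature_errors_max,
                  cr$mature_biased_bulges_max, cr$mature_in_stem_min),
    direction = c(">=", "<=", "<=", "<=", ">=", "<=", "<=", ">=", "<=",
                  "<=", ">=")
  )
  rows$pass <- ifelse(rows$direction == ">=", rows$value >= rows$threshold,
                      rows$value <= rows$threshold)
  structure(rows, class = c("criterion_report", "data.frame"),
            overall = all(rows$pass))
}

#' Overall verdict of a criterion report
#'
#' @param report a `criterion_report`.
#' @return `TRUE` when all eleven criteria pass.
#' @export
criteria_pass <- function(report) isTRUE(attr(report, "overall"))

#' @export
print.criterion_report <- function(x, ...) {
  print.data.frame(x)
  cat("overall:", if (attr(x, "overall")) "PASS" else
    paste0("FAIL (criteria ", paste(x$id[!x$pass], collapse = ","), ")"),
    "\n")
  invisible(x)
}

#' Annotate conserved miRNAs in a library
#'
#' Each unique read matching a reference mature miRNA (allowing end shifts
#' and one mismatch, see [map_to_mature_refs()]) becomes a conserved record
#' named after its best reference hit with the species prefix `csl-`. When
#' the read also maps to the genome and some mapped locus folds into a
#' hairpin with the read in a stem arm, that locus is attached and the
#' record is confirmed; otherwise it is flagged `unconfirmed`.
#'
#' @param lib a `smrna_library`.
#' @param catalog reference `mirna_catalog`.
#' @param genome_index a [build_index()] (or `NULL`: all records
#'   unconfirmed).
#' @param max_shift,max_mm matching tolerances against the references.
#' @param flank precursor window flank (nt).
#' @param min_in_stem percent-in-stem required to call "in a hairpin arm".
#' @return data.frame of conserved records: `name`, `reference`, `family`,
#'   `sequence`, `class`, `count`, `confirmed`, and locus columns
#'   (`contig`, `start`, `end`, `strand`; `NA` when unconfirmed).
#' @export
annotate_conserved <- function(lib, catalog, genome_index = NULL,
                               max_shift = 3L, max_mm = 1L, flank = 120L,
                               min_in_stem = 80) {
  ur <- lib$unique_reads
  out <- list()
  used_names <- character(0)
  genome <- if (!is.null(genome_index))
    setNames(as.character(genome_index$contigs),
             names(genome_index$lengths))
  for (i in seq_len(nrow(ur))) {
    s <- ur$sequence[i]
    hits <- map_to_mature_refs(s, catalog, max_shift = max_shift,
                               max_mm = max_mm)
    if (nrow(hits) == 0L) next
    ref <- hits$name[1L]
    name <- paste0("csl-", sub("^[a-z]{3,4}-", "", ref))
    if (name %in% used_names) {   # distinct isoforms of one reference
      k <- 1L
      while (paste0(name, "-", k) %in% used_names) k <- k + 1L
      name <- paste0(name, "-", k)
    }
    used_names <- c(used_names, name)
    locus <- data.frame(contig = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_)
    confirmed <- FALSE
    if (!is.null(genome_index)) {
      gh <- map_read(s, genome_index, max_mm = max_mm)
      for (h in seq_len(nrow(gh))) {
        win <- extract_window(genome, gh[h, ], flank = flank)
        fr <- fold(win$sequence)
        ft <- extract_features(fr, win$mature_start, win$mature_end)
        if (ft$mature_in_stem >= min_in_stem && ft$arm %in% c("5p", "3p")) {
          locus <- gh[h, c("contig", "start", "end", "strand")]
          confirmed <- TRUE
          break
        }
      }
    }
    out[[length(out) + 1L]] <- cbind(
      data.frame(name = name, reference = ref,
                 family = assign_family_name(ref),
                 sequence = s, class = "conserved", count = ur$count[i],
                 confirmed = confirmed),
      locus)
  }
  if (length(out) == 0L) {
    return(data.frame(name = character(), reference = character(),
                      family = character(), sequence = character(),
                      class = character(), count = integer(),
                      confirmed = logical(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

#' Discover novel miRNAs through the hairpin criterion filter
#'
#' For every genome locus of each candidate read the flanked window is
#' extracted, folded and measured; loci passing all eleven criteria make
#' the read a novel miRNA. One record is kept per unique read (the
#' best-scoring locus: most criteria satisfied with strict margin, ties
#' broken by the leftmost locus). Records are named `csl-nmiR1`,
#' `csl-nmiR2`, ... in order of descending read count then sequence.
#'
#' @param lib a `smrna_library` (reads already annotated as conserved
#'   should be excluded by the caller via `exclude`).
#' @param genome_index a [build_index()] object.
#' @param criteria a [novel_criteria()] threshold set.
#' @param exclude character vector of sequences to skip (e.g. conserved).
#' @param min_count minimum pooled read count for a candidate (default 2:
#'   singleton reads are not credible precursor evidence).
#' @param max_mm mismatches allowed for genome mapping.
#' @param flank precursor window flank (nt).
#' @return data.frame of novel records: `name`, `family`, `sequence`,
#'   `class`, `count`, locus columns and `structure` (dot-bracket of the
#'   precursor window) plus `energy`.
#' @export
discover_novel <- function(lib, genome_index, criteria = novel_criteria(),
                           exclude = character(), min_count = 2L,
                           max_mm = 1L, flank = 120L) {
  ur <- lib$unique_reads
  ur <- ur[!(ur$sequence %in% exclude) & ur$count >= min_count, ,
           drop = FALSE]
  ## candidate order fixes naming: descending count, then sequence
  ur <- ur[order(-ur$count, ur$sequence), , drop = FALSE]
  genome <- setNames(as.character(genome_index$contigs),
                     names(genome_index$lengths))
  out <- list()
  for (i in seq_len(nrow(ur))) {
    s <- ur$sequence[i]
    if (nchar(s) < genome_index$k) next
    gh <- map_read(s, genome_index, max_mm = max_mm)
    best <- NULL
    for (h in seq_len(nrow(gh))) {
      win <- extract_window(genome, gh[h, ], flank = flank)
      fr <- fold(win$sequence)
      ft <- extract_features(fr, win$mature_start, win$mature_end)
      rep <- evaluate_criteria(ft, criteria)
      if (!criteria_pass(rep)) next
      ## margin score: criteria satisfied strictly beyond their threshold
      margin <- sum(ifelse(rep$direction == ">=", rep$value > rep$threshold,
                           rep$value < rep$threshold))
      if (is.null(best) || margin > best$margin) {
        best <- list(hit = gh[h, ], fold = fr, margin = margin)
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(sequence = s, class = "novel", count = ur$count[i]),
        best$hit[, c("contig", "start", "end", "strand")],
        data.frame(structure = best$fold$structure,
                   energy = best$fold$energy))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(name = character(), family = character(),
                      sequence = character(), class = character(),
                      count = integer(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), structure = character(),
                      energy = numeric()))
  }
  d <- do.call(rbind, out)
  d$name <- paste0("csl-nmiR", seq_len(nrow(d)))
  d$family <- d$name
  rownames(d) <- NULL
  d[, c("name", "family", "sequence", "class", "count", "contig", "start",
        "end", "strand", "structure", "energy")]
}

## family token from a (reference) miRNA name: "miR" + leading integer run,
## case-insensitive; NA when unparseable
assign_family_name <- function(name) {
  m <- regmatches(name, regexpr("(?i)mir[0-9]+", name, perl = TRUE))
  if (length(m) == 0L) return(NA_character_)
  paste0("miR", sub("(?i)^mir", "", m, perl = TRUE))
}

#' Assign a family label to a miRNA record
#'
#' Conserved records inherit the family token of their reference name
#' (`"miR"` plus the leading integer run, parsed case-insensitively, so
#' `csl-miR166a-5p-1` and `csl-MIR166b-3p` both yield `miR166`). Novel
#' records are their own family.
#'
#' @param name miRNA (or reference) name.
#' @param class `"conserved"` or `"novel"`.
#' @return family label.
#' @export
assign_family <- function(name, class = "conserved") {
  stopifnot(length(name) == length(class) || length(class) == 1L)
  class <- rep_len(class, length(name))
  out <- character(length(name))
  for (i in seq_along(name)) {
    if (class[i] == "novel") {
      out[i] <- name[i]
    } else {
      fam <- assign_family_name(name[i])
      if (is.na(fam)) {
        stop("cannot parse family from conserved miRNA name: ", name[i],
             call. = FALSE)
      }
      out[i] <- fam
    }
  }
  out
}

#' Family and length statistics of a miRNA catalog
#'
#' @param catalog a `mirna_catalog` (families present or derivable from
#'   names).
#' @return list with `n_families` (conserved families), `members` (named
#'   member counts per conserved family), `largest_family` and its size,
#'   `singleton_percent` (percent of conserved families with one member,
#'   two decimals), `n_conserved`, `n_novel`, and `length_histogram`
#'   (counts by mature length over all records).
#' @export
family_stats <- function(catalog) {
  fam <- if ("family" %in% names(catalog) && !anyNA(catalog$family)) {
    catalog$family
  } else {
    assign_family(catalog$name, catalog$class)
  }
  cons <- catalog$class == "conserved"
  members <- table(fam[cons])
  if (length(members)) {
    members <- members[order(-as.integer(members), names(members))]
  }
  lens <- table(factor(nchar(catalog$sequence),
                       levels = seq(min(nchar(catalog$sequence)),
                                    max(nchar(catalog$sequence)))))
  list(
    n_families = length(members),
    members = members,
    largest_family = if (length(members)) names(members)[1L] else NA,
    largest_size = if (length(members)) as.integer(members[1L]) else 0L,
    singleton_percent = if (length(members))
      round(100 * sum(members == 1L) / length(members), 2L) else NA_real_,
    n_conserved = sum(cons),
    n_novel = sum(catalog$class == "novel"),
    length_histogram = lens
  )
}
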