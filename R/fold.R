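## Bundled deterministic RNA secondary-structure backend: maximum
## base-pairing (Nussinov dynamic programming, minimum hairpin loop 3,
## G:U wobble allowed) with a nearest-neighbor stacking tie-break, and an
## energy estimate summing the stacking contributions of the predicted
## structure. An external folding program can be plugged in as a function
## satisfying the same output contract.

## pair type order used throughout: AT TA GC CG GT TG (DNA alphabet; T
## stands for U). Stacking free energies in kcal/mol for an outer pair
## stacked on an inner pair; all strictly negative, so every added stack
## strictly lowers the energy and an unstacked (isolated) pair contributes
## nothing.
.pair_types <- c("AT", "TA", "GC", "CG", "GT", "TG")
.stack_energy <- matrix(c(
  -0.9, -1.1, -2.1, -2.2, -0.6, -1.4,
  -1.3, -0.9, -2.1, -2.4, -1.0, -1.3,
  -2.4, -2.2, -3.3, -3.4, -1.5, -2.5,
  -2.1, -2.1, -2.4, -3.3, -1.4, -2.1,
  -1.3, -1.4, -2.1, -2.5, -0.5, -0.4,
  -1.0, -0.6, -1.4, -1.5, -0.3, -0.5),
  nrow = 6L, byrow = TRUE, dimnames = list(.pair_types, .pair_types))

.base_code <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], .base_alphabet) - 1L
  code[is.na(code)] <- -1L
  code
}

.pair_type_of <- function(a, b) {
  pt <- paste0(a, b)
  match(pt, .pair_types)   # NA when not a legal pair
}

#' Parse a dot-bracket string into a pair table
#'
#' @param structure dot-bracket string (`(`, `)`, `.`).
#' @return integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or 0 when unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (length(open) == 0L) stop("unbalanced brackets", call. = FALSE)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j; pt[j] <- i
    } else if (ch[i] != ".") stop("illegal structure character: ", ch[i],
                                  call. = FALSE)
  }
  if (length(open)) stop("unbalanced brackets", call. = FALSE)
  pt
}

#' Render a pair table as dot-bracket
#'
#' @param pt integer pair table as returned by [pair_table()].
#' @return dot-bracket string.
#' @export
dot_bracket <- function(pt) {
  ch <- rep(".", length(pt))
  ch[pt > seq_along(pt)] <- "("
  ch[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(ch, collapse = "")
}

#' Stacking-sum energy of a structure
#'
#' Sums the bundled nearest-neighbor stacking contributions over every
#' stacked pair of adjacent base pairs; isolated pairs contribute zero.
#'
#' @param seq sequence (DNA alphabet).
#' @param structure dot-bracket string of the same length.
#' @return energy estimate in kcal/mol (always <= 0).
#' @export
structure_energy <- function(seq, structure) {
  seq <- norm_seq(seq)
  pt <- pair_table(structure)
  b <- strsplit(seq, "")[[1]]
  stopifnot(length(b) == length(pt))
  e <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j <= i) next
    if (i + 1L <= length(pt) && pt[i + 1L] == j - 1L && j - 1L > i + 1L) {
      outer <- .pair_type_of(b[i], b[j])
      inner <- .pair_type_of(b[i + 1L], b[j - 1L])
      if (!is.na(outer) && !is.na(inner)) {
        e <- e + .stack_energy[outer, inner]
      }
    }
  }
  e
}

#' Fold a sequence into its predicted secondary structure
#'
#' The bundled backend computes the maximum base-pair structure (dynamic
#' programming; minimum hairpin loop 3 nt; allowed pairs A:U, G:C and G:U)
#' breaking ties toward the most stacked (most helix-like) structure, and
#' reports the stacking-sum energy of the result. Alternatively `backend`
#' may be a function `function(seq)` returning a list with elements
#' `structure` (dot-bracket) and `energy`; its output is validated against
#' the same invariants.
#'
#' @param seq sequence to fold (DNA or RNA alphabet).
#' @param backend `"bundled"` or a plug-in folding function.
#' @return a `fold_result`: list with `sequence`, `structure` (dot-bracket),
#'   `energy` (kcal/mol, <= 0) and `pairs` (base-pair count).
#' @export
#' @examples
#' fold("GGGGAAAACCCC")
fold <- function(seq, backend = "bundled") {
  seq <- norm_seq(seq)
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("illegal character in sequence", call. = FALSE)
  }
  if (is.function(backend)) {
    out <- backend(seq)
    fr <- fold_result(seq, out$structure, out$energy)
    return(fr)
  }
  stopifnot(identical(backend, "bundled"))
  bonus <- matrix(as.integer(round(-100 * .stack_energy)), 6L, 6L)
  pt <- .nussinov_fold(.base_code(seq), bonus, 3L)
  structure_str <- dot_bracket(pt)
  fold_result(seq, structure_str, structure_energy(seq, structure_str))
}

#' Construct and validate a fold result
#'
#' Enforces the structural invariants every folding backend must satisfy:
#' balanced brackets, complementarity of every paired position (A:U, G:C,
#' G:U), minimum hairpin loop of 3 nt and a non-positive energy.
#'
#' @param sequence folded sequence.
#' @param structure dot-bracket string.
#' @param energy energy estimate in kcal/mol.
#' @return a `fold_result` list.
#' @export
fold_result <- function(sequence, structure, energy) {
  sequence <- norm_seq(sequence)
  stopifnot(nchar(sequence) == nchar(structure), is.finite(energy),
            energy <= 0)
  pt <- pair_table(structure)
  b <- strsplit(sequence, "")[[1]]
  for (i in which(pt > seq_along(pt))) {
    j <- pt[i]
    if (is.na(.pair_type_of(b[i], b[j]))) {
      stop("non-complementary pair ", b[i], ":", b[j], " at ", i, "-", j,
           call. = FALSE)
    }
    if (j - i - 1L < 3L) stop("hairpin loop shorter than 3 nt",
                              call. = FALSE)
  }
  structure(list(sequence = sequence, structure = structure,
                 energy = energy, pairs = sum(pt > 0) / 2L),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$energy),
      " kcal/mol, ", x$pairs, " bp)\n", sep = "")
  invisible(x)
}

#' Write dot-bracket structures to a file
#'
#' One three-line block per record: `>id`, sequence, structure with the
#' energy appended in parentheses.
#'
#' @param ids,folds parallel vectors: identifiers and `fold_result`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot_bracket <- function(ids, folds, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    writeLines(c(paste0(">", ids[i]), f$sequence,
                 sprintf("%s (%.2f)", f$structure, f$energy)), con)
  }
  invisible(path)
}
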