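## Expression normalization, condition fold-changes and the qRT-PCR
## 2^-ddCt arithmetic used for validation.

#' Reads-per-million normalization
#'
#' @param counts nonnegative numeric vector of read counts.
#' @return `1e6 * counts / sum(counts)`; an all-zero input returns zeros
#'   with a warning.
#' @export
normalize_rpm <- function(counts) {
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) {
    warning("zero total count; returning all-zero RPM vector")
    return(numeric(length(counts)) * 0)
  }
  1e6 * counts / tot
}

#' Log2 fold-change with a pseudocount
#'
#' @param rpm_cg,rpm_ag normalized expression under the two conditions
#'   (treatment over control).
#' @param pseudo pseudocount added to both (default 1).
#' @return `log2((rpm_cg + pseudo) / (rpm_ag + pseudo))`.
#' @export
log2_fold_change <- function(rpm_cg, rpm_ag, pseudo = 1) {
  stopifnot(pseudo > 0)
  log2((rpm_cg + pseudo) / (rpm_ag + pseudo))
}

#' Build a per-miRNA expression table across two conditions
#'
#' @param counts_ag,counts_cg named integer vectors of per-miRNA read
#'   counts in the control (AG) and treatment (CG) libraries; names are
#'   unioned, absent entries count 0.
#' @param pseudo pseudocount for the fold-change.
#' @return data.frame with `mirna`, `count_AG`, `count_CG`, `rpm_AG`,
#'   `rpm_CG` and `log2fc` (CG over AG).
#' @export
expression_table <- function(counts_ag, counts_cg, pseudo = 1) {
  ids <- union(names(counts_ag), names(counts_cg))
  a <- setNames(rep(0, length(ids)), ids); a[names(counts_ag)] <- counts_ag
  b <- setNames(rep(0, length(ids)), ids); b[names(counts_cg)] <- counts_cg
  rpm_a <- normalize_rpm(a)
  rpm_b <- normalize_rpm(b)
  data.frame(mirna = ids, count_AG = as.numeric(a), count_CG = as.numeric(b),
             rpm_AG = rpm_a, rpm_CG = rpm_b,
             log2fc = log2_fold_change(rpm_b, rpm_a, pseudo),
             row.names = NULL)
}

#' Relative expression from qRT-PCR triplicates (2^-ddCt)
#'
#' Per condition, `dCt = mean Ct(target) - mean Ct(reference U4)`; the
#' relative expression of the treatment over the control is
#' `2^-(dCt_CG - dCt_AG)`.
#'
#' @param ct_target_ag,ct_target_cg numeric Ct triplicates for the target
#'   miRNA under the two conditions.
#' @param ct_ref_ag,ct_ref_cg Ct triplicates for the reference gene (U4).
#' @return relative expression (fold-change CG over AG).
#' @export
relative_expression <- function(ct_target_ag, ct_target_cg,
                                ct_ref_ag, ct_ref_cg) {
  for (v in list(ct_target_ag, ct_target_cg, ct_ref_ag, ct_ref_cg)) {
    if (length(v) == 0L || anyNA(v)) {
      stop("missing Ct measurements (reference or target)", call. = FALSE)
    }
    if (any(v <= 0)) stop("Ct values must be positive", call. = FALSE)
  }
  dct_ag <- mean(ct_target_ag) - mean(ct_ref_ag)
  dct_cg <- mean(ct_target_cg) - mean(ct_ref_cg)
  2^-(dct_cg - dct_ag)
}

#' Squared Pearson correlation between sequencing and qPCR fold-changes
#'
#' Computed on the log2 scale, the scale on which fold-changes from the
#' two platforms are compared.
#'
#' @param seq_fc,qpcr_fc paired fold-change vectors (linear scale),
#'   length >= 3.
#' @return R squared.
#' @export
validation_r2 <- function(seq_fc, qpcr_fc) {
  stopifnot(length(seq_fc) == length(qpcr_fc), length(seq_fc) >= 3L)
  x <- log2(seq_fc)
  y <- log2(qpcr_fc)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in fold-changes; R2 undefined", call. = FALSE)
  }
  cor(x, y)^2
}

#' @importFrom stats sd
NULL
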