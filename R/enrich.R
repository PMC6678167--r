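## Term (GO-like / pathway-like) over-representation of predicted target
## genes: hypergeometric upper-tail p-values and rich factors.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` carry the term. Computed in log space by
#' `stats::phyper`.
#'
#' @param k target genes carrying the term.
#' @param n annotated target genes drawn.
#' @param K background genes carrying the term.
#' @param N annotated background genes.
#' @return the upper-tail p-value.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (k > n || n > N || k > K || K > N || min(k, n, K, N) < 0) {
    stop("inconsistent hypergeometric counts: k=", k, " n=", n,
         " K=", K, " N=", N, call. = FALSE)
  }
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Term over-representation of a target gene set
#'
#' One row per term carried by at least one annotated target gene. Genes
#' without any annotation are excluded from both the draw size `n` and the
#' background size `N`. Raw p-values carry significance flags at 0.05 and
#' 0.01; Benjamini-Hochberg q-values are emitted additionally.
#'
#' @param target_genes character vector of predicted target gene ids.
#' @param annotation a [read_annotation()] list (`genes`, `labels`,
#'   `namespace`).
#' @param background optional character vector of background gene ids;
#'   default: all annotated genes.
#' @return data.frame sorted by p ascending with columns `term`, `label`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `rich_factor` (= k/K), `sig05`,
#'   `sig01`.
#' @export
enrich_terms <- function(target_genes, annotation, background = NULL) {
  if (is.null(annotation$genes) || length(annotation$genes) == 0L) {
    stop("empty annotation", call. = FALSE)
  }
  if (is.null(background)) background <- names(annotation$genes)
  background <- intersect(background, names(annotation$genes))
  N <- length(background)
  targets <- intersect(unique(target_genes), background)
  n <- length(targets)
  term2bg <- table(unlist(annotation$genes[background]))
  hit_terms <- unique(unlist(annotation$genes[targets]))
  if (length(hit_terms) == 0L) {
    return(data.frame(term = character(), label = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      rich_factor = numeric(), sig05 = logical(),
                      sig01 = logical()))
  }
  term2k <- table(unlist(annotation$genes[targets]))
  rows <- data.frame(
    term = hit_terms,
    label = unname(ifelse(hit_terms %in% names(annotation$labels),
                          annotation$labels[hit_terms], hit_terms)),
    k = as.integer(term2k[hit_terms]),
    n = n,
    K = as.integer(term2bg[hit_terms]),
    N = N
  )
  rows$p <- mapply(hypergeom_tail, rows$k, rows$n, rows$K, rows$N)
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$rich_factor <- rows$k / rows$K
  rows$sig05 <- rows$p < 0.05
  rows$sig01 <- rows$p < 0.01
  rows <- rows[order(rows$p, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
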