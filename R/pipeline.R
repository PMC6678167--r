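## End-to-end orchestration: preprocess -> map -> identify (conserved,
## novel) -> family stats -> targets -> quantify -> enrich, emitting the
## report tables (library summary, catalog, family/length statistics,
## target table, enrichment table) as TSV files.

#' Assemble and validate a pipeline configuration
#'
#' Paths may be given as files on disk or as in-memory objects (read
#' vectors, named sequence vectors, annotation lists); thresholds are
#' validated against their documented ranges.
#'
#' @param fastq named list with elements `AG` and `CG`: FASTQ paths or raw
#'   read vectors.
#' @param genome genome FASTA path or named contig vector.
#' @param catalog reference catalog path or `mirna_catalog` (may be `NULL`
#'   to skip conserved annotation).
#' @param transcriptome transcript FASTA path or named vector (`NULL`
#'   skips target prediction).
#' @param annotation annotation TSV path or [read_annotation()] list
#'   (`NULL` skips enrichment).
#' @param adapter 3' adapter sequence.
#' @param criteria a [novel_criteria()].
#' @param cutoff target-site penalty cutoff.
#' @param flank precursor window flank (nt).
#' @param max_shift,max_mm reference-matching tolerances.
#' @param out_dir output directory for the report TSVs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fastq, genome, catalog = NULL,
                            transcriptome = NULL, annotation = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            criteria = novel_criteria(), cutoff = 4,
                            flank = 120L, max_shift = 3L, max_mm = 1L,
                            out_dir = tempfile("mirseed_run_")) {
  stopifnot(all(c("AG", "CG") %in% names(fastq)), cutoff >= 0,
            flank >= 0L, max_shift >= 0L, max_mm %in% c(0L, 1L))
  for (p in c(fastq, list(genome, catalog, transcriptome, annotation))) {
    if (is.character(p) && length(p) == 1L && grepl("[/\\\\]", p) &&
        !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(fastq = fastq, genome = genome, catalog = catalog,
                 transcriptome = transcriptome, annotation = annotation,
                 adapter = adapter, criteria = criteria, cutoff = cutoff,
                 flank = as.integer(flank), max_shift = as.integer(max_shift),
                 max_mm = as.integer(max_mm), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full identification and characterization pipeline
#'
#' Stages run in order: preprocessing of both condition libraries,
#' genome-index construction, conserved annotation (when a reference
#' catalog is configured), novel discovery through the eleven-criterion
#' filter, family and length statistics, target prediction (when a
#' transcriptome is configured), expression quantification, and term
#' enrichment of the predicted target genes (when an annotation is
#' configured). Every report table is written to `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with `libraries`, `catalog`, `stats`,
#'   `expression`, `targets`, `enrichment`, `summaries` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pcfg <- preprocess_config(adapter = config$adapter)
  stage <- function(name, expr) {
    message("[mirseed] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  libs <- stage("preprocess", lapply(c(AG = "AG", CG = "CG"), function(cc) {
    preprocess_fastq(config$fastq[[cc]], condition = cc, config = pcfg)
  }))
  idx <- stage("index", build_index(config$genome))

  refcat <- config$catalog
  if (is.character(refcat) && length(refcat) == 1L) {
    refcat <- parse_mirna_catalog(refcat)
  }
  ## identification runs on the union of the two condition libraries
  pooled <- collapse_unique(rep(
    c(libs$AG$unique_reads$sequence, libs$CG$unique_reads$sequence),
    c(libs$AG$unique_reads$count, libs$CG$unique_reads$count)))
  pooled_lib <- smrna_library(pooled, condition = "pooled")

  conserved <- if (!is.null(refcat)) {
    stage("conserved", annotate_conserved(
      pooled_lib, refcat, idx, max_shift = config$max_shift,
      max_mm = config$max_mm, flank = config$flank))
  } else {
    annotate_conserved(pooled_lib,
                       mirna_catalog(data.frame(family = character(),
                                                name = character(),
                                                sequence = character(),
                                                class = character())),
                       NULL)
  }
  novel <- stage("novel", discover_novel(
    pooled_lib, idx, criteria = config$criteria,
    exclude = conserved$sequence, max_mm = config$max_mm,
    flank = config$flank))

  cols <- c("name", "family", "sequence", "class", "count", "contig",
            "start", "end", "strand")
  catalog <- rbind(conserved[, cols], novel[, cols])
  stats <- stage("family_stats", family_stats(catalog))

  counts <- lapply(libs, function(l) {
    ur <- l$unique_reads
    setNames(ur$count, ur$sequence)[catalog$sequence]
  })
  expr <- stage("quantify", expression_table(
    setNames(ifelse(is.na(counts$AG), 0, counts$AG), catalog$name),
    setNames(ifelse(is.na(counts$CG), 0, counts$CG), catalog$name)))

  targets <- NULL
  enrichment <- NULL
  if (!is.null(config$transcriptome)) {
    targets <- stage("targets", predict_targets(
      catalog, config$transcriptome, cutoff = config$cutoff))
    ann <- config$annotation
    if (is.character(ann) && length(ann) == 1L) {
      ann <- read_annotation(ann)
    }
    if (!is.null(ann) && nrow(targets)) {
      enrichment <- stage("enrich", enrich_terms(unique(targets$gene), ann))
    }
  }

  summaries <- stage("report", lapply(libs, summarize_library,
                                      genome_index = idx))
  wt <- function(d, f) {
    write.table(d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (cc in names(summaries)) {
    wt(summaries[[cc]], paste0("library_summary_", cc, ".tsv"))
  }
  wt(catalog, "mirna_catalog.tsv")
  wt(data.frame(family = names(stats$members),
                members = as.integer(stats$members)), "family_stats.tsv")
  wt(data.frame(length = names(stats$length_histogram),
                count = as.integer(stats$length_histogram)),
     "length_histogram.tsv")
  wt(expr, "expression.tsv")
  if (!is.null(targets)) wt(targets, "targets.tsv")
  if (!is.null(enrichment)) wt(enrichment, "enrichment.tsv")
  loci <- catalog[!is.na(catalog$start), , drop = FALSE]
  if (nrow(loci)) {
    loci$id <- loci$name
    write_gff(loci, file.path(config$out_dir, "precursors.gff3"))
  }

  invisible(list(libraries = libs, catalog = catalog, stats = stats,
                 expression = expr, targets = targets,
                 enrichment = enrichment, summaries = summaries,
                 out_dir = config$out_dir))
}
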