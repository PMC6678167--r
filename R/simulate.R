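## Synthetic study generator: random genomes with planted criterion-passing
## hairpin precursors, two-condition small-RNA read libraries, transcriptomes
## with planted target sites of prescribed penalty, gene-term annotations and
## matched qPCR measurements — all with full ground truth, so that every
## pipeline stage is testable without external data.
##
## A single master seed governs a run; each stage draws from a named
## substream derived from it, so stages are reproducible independently.

#' Generate a random genome
#'
#' @param length genome length in nt (>= 1000).
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @param name contig name.
#' @return named character vector of one contig.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, name = "chr1") {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    setNames(paste(sample(names(p), length, replace = TRUE, prob = p),
                   collapse = ""), name)
  })
}

#' Random mature miRNA sequences
#'
#' @param n number of sequences.
#' @param len length in nt (recycled).
#' @param seed RNG seed.
#' @return character vector named `mir1`, `mir2`, ...
#' @export
random_matures <- function(n, len = 21L, seed = 1L) {
  len <- rep_len(len, n)
  with_seed(seed, {
    setNames(vapply(seq_len(n), function(i) {
      paste(sample(.base_alphabet, len[i], replace = TRUE), collapse = "")
    }, ""), paste0("mir", seq_len(n)))
  })
}

## construct one precursor: mature + linker loop + (possibly imperfect)
## reverse complement of the mature
.make_precursor <- function(mature, loop_len) {
  linker <- paste(sample(.base_alphabet, loop_len, replace = TRUE),
                  collapse = "")
  paste0(mature, linker, revcomp(mature))
}

#' Plant criterion-passing hairpin precursors in a genome
#'
#' For each mature sequence a precursor (mature + linker loop + reverse
#' complement) is built and written over a random genome slice, keeping
#' planted loci disjoint and well separated. Each insertion is verified by
#' running the discovery machinery itself on the flanked window
#' ([fold()], [extract_features()], [evaluate_criteria()]); failing
#' linkers/loci are resampled up to `max_tries` times.
#'
#' @param genome named character vector (single or multiple contigs).
#' @param mature_seqs named character vector of mature sequences
#'   (18-25 nt).
#' @param seed RNG seed.
#' @param loop_len linker loop length (>= 8 nt; default 12).
#' @param flank discovery window flank the verification uses (default 120).
#' @param criteria [novel_criteria()] the planted windows must pass.
#' @param max_tries resampling budget per mature sequence.
#' @return list with `genome` (modified) and `truth`: data.frame `name`,
#'   `sequence`, `contig`, `start`, `end` (mature span, 0-based
#'   half-open), `strand`, `precursor_start`, `precursor_end`.
#' @export
plant_hairpins <- function(genome, mature_seqs, seed = 1L, loop_len = 12L,
                           flank = 120L, criteria = novel_criteria(),
                           max_tries = 50L) {
  stopifnot(loop_len >= 8L, all(nchar(mature_seqs) >= 18L),
            all(nchar(mature_seqs) <= 25L))
  if (is.null(names(mature_seqs))) {
    names(mature_seqs) <- paste0("mir", seq_along(mature_seqs))
  }
  contig <- names(genome)[1L]
  gseq <- genome[[1L]]
  glen <- nchar(gseq)
  occupied <- IRanges::IRanges()
  truth <- list()
  with_seed(seed, {
    for (nm in names(mature_seqs)) {
      m <- norm_seq(mature_seqs[[nm]])
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        prec <- .make_precursor(m, loop_len)
        lp <- nchar(prec)
        pos <- sample.int(glen - lp - 2L * flank, 1L) + flank  # 0-based
        cand <- IRanges::IRanges(pos - flank + 1L, pos + lp + flank)
        if (length(IRanges::findOverlaps(cand, occupied)) > 0L) next
        gnew <- paste0(substr(gseq, 1L, pos),
                       prec, substr(gseq, pos + lp + 1L, glen))
        hit <- data.frame(contig = contig, start = pos,
                          end = pos + nchar(m), strand = "+")
        win <- extract_window(setNames(gnew, contig), hit, flank = flank)
        ft <- extract_features(fold(win$sequence),
                               win$mature_start, win$mature_end)
        if (!criteria_pass(evaluate_criteria(ft, criteria))) next
        gseq <- gnew
        occupied <- c(occupied, cand)
        truth[[length(truth) + 1L]] <- data.frame(
          name = nm, sequence = m, contig = contig, start = pos,
          end = pos + nchar(m), strand = "+", precursor_start = pos,
          precursor_end = pos + lp)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not plant a criterion-passing precursor for ", nm,
             " (", m, ") within ", max_tries, " tries", call. = FALSE)
      }
    }
  })
  genome[[1L]] <- gseq
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

#' Simulate two-condition small-RNA read libraries
#'
#' Read counts per planted miRNA are multinomial within each condition;
#' condition CG reweights miRNA `i` by `fold_changes[i]`. A small fraction
#' of reads are random-noise 18-25-mers. Each read is the mature sequence
#' (with a rare 1-nt 3' trim) plus the 3' adapter; qualities are constant.
#'
#' @param truth `truth` data.frame from [plant_hairpins()].
#' @param depth reads per condition (>= 100).
#' @param fold_changes per-miRNA CG/AG expression ratios (recycled;
#'   default 1).
#' @param adapter 3' adapter to append.
#' @param noise_frac fraction of noise reads in `[0, 1)`.
#' @param shift_prob probability of a 1-nt 3' end trim.
#' @param seed RNG seed.
#' @return list with `reads` (list `AG`, `CG` of read character vectors),
#'   `true_counts` (matrix miRNA x condition) and `weights`.
#' @export
simulate_reads <- function(truth, depth = 50000L, fold_changes = 1,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           noise_frac = 0.05, shift_prob = 0.02,
                           seed = 1L) {
  stopifnot(depth >= 100L, noise_frac >= 0, noise_frac < 1)
  n <- nrow(truth)
  fc <- rep_len(fold_changes, n)
  with_seed(seed, {
    w <- stats::rgamma(n, shape = 5, rate = 1)   # baseline abundances
    w <- w / sum(w)
    n_noise <- round(depth * noise_frac)
    n_sig <- depth - n_noise
    mk_reads <- function(prob) {
      counts <- as.integer(rmultinom(1L, n_sig, prob))
      reads <- rep(truth$sequence, counts)
      trim <- runif(length(reads)) < shift_prob & nchar(reads) > 18L
      reads[trim] <- substr(reads[trim], 1L, nchar(reads[trim]) - 1L)
      noise <- vapply(sample(18:25, n_noise, replace = TRUE), function(l) {
        paste(sample(.base_alphabet, l, replace = TRUE), collapse = "")
      }, "")
      list(reads = paste0(sample(c(reads, noise)), adapter),
           counts = counts)
    }
    ag <- mk_reads(w)
    cg <- mk_reads(w * fc / sum(w * fc))
    tc <- cbind(AG = ag$counts, CG = cg$counts)
    rownames(tc) <- truth$name
    list(reads = list(AG = ag$reads, CG = cg$reads), true_counts = tc,
         weights = w, fold_changes = fc)
  })
}

## choose defect positions reaching a prescribed penalty total exactly;
## returns data.frame(position, kind) or NULL when unreachable
.spec_defects <- function(total, mirna) {
  L <- nchar(mirna)
  m <- strsplit(mirna, "")[[1]]
  outside <- setdiff(seq_len(L), 2:13)
  inside <- intersect(seq_len(L), 2:13)
  gu_ok <- which(m %in% c("G", "T"))
  defects <- list()
  used <- integer(0)
  rem <- total
  take <- function(pool) setdiff(pool, used)[1L]
  while (rem >= 2 && !is.na(take(inside))) {
    p <- take(inside); used <- c(used, p)
    defects[[length(defects) + 1L]] <- data.frame(position = p, kind = "MM")
    rem <- rem - 2
  }
  while (rem >= 1 && !is.na(take(outside))) {
    p <- take(outside); used <- c(used, p)
    defects[[length(defects) + 1L]] <- data.frame(position = p, kind = "MM")
    rem <- rem - 1
  }
  while (rem >= 0.5 && !is.na(take(intersect(outside, gu_ok)))) {
    p <- take(intersect(outside, gu_ok)); used <- c(used, p)
    defects[[length(defects) + 1L]] <- data.frame(position = p, kind = "GU")
    rem <- rem - 0.5
  }
  if (rem != 0) return(NULL)
  if (length(defects) == 0L) {
    return(data.frame(position = integer(), kind = character()))
  }
  do.call(rbind, defects)
}

## build a site sequence for mirna with the given defects
.site_with_defects <- function(mirna, defects) {
  m <- strsplit(mirna, "")[[1]]
  L <- length(m)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  site <- rev(vapply(m, function(b) comp[[b]], ""))  # perfect complement
  for (i in seq_len(nrow(defects))) {
    p <- defects$position[i]
    j <- L - p + 1L           # site index facing miRNA position p
    if (defects$kind[i] == "GU") {
      site[j] <- if (m[p] == "G") "T" else "G"
    } else {
      bad <- setdiff(.base_alphabet, c(comp[[m[p]]],
                                       if (m[p] == "G") "T",
                                       if (m[p] == "T") "G"))
      site[j] <- bad[1L]
    }
  }
  paste(site, collapse = "")
}

#' Plant target sites of prescribed penalty into a transcriptome
#'
#' For each entry of `score_spec` a site whose [score_duplex()] total
#' equals the prescribed value exactly is embedded into its own random
#' transcript, cycling through the catalog miRNAs. Sites above the
#' reporting cutoff serve as negative controls. Remaining transcripts are
#' site-free background.
#'
#' @param transcript_count number of transcripts (>= planted sites).
#' @param catalog `mirna_catalog` (or data.frame with `name`, `sequence`).
#' @param score_spec numeric vector of prescribed penalty totals.
#' @param transcript_len transcript length in nt.
#' @param seed RNG seed.
#' @return list with `transcripts` (named character vector) and `truth`
#'   (data.frame `mirna`, `gene`, `start`, `end`, `total`).
#' @export
plant_target_sites <- function(transcript_count, catalog,
                               score_spec = c(0, 2, 4, 5),
                               transcript_len = 500L, seed = 1L) {
  stopifnot(transcript_count >= length(score_spec))
  with_seed(seed, {
    tx <- vapply(seq_len(transcript_count), function(i) {
      paste(sample(.base_alphabet, transcript_len, replace = TRUE),
            collapse = "")
    }, "")
    names(tx) <- paste0("gene", seq_len(transcript_count))
    truth <- list()
    for (s in seq_along(score_spec)) {
      mi <- (s - 1L) %% nrow(catalog) + 1L
      mirna <- catalog$sequence[mi]
      defects <- .spec_defects(score_spec[s], mirna)
      if (is.null(defects)) {
        stop("penalty total ", score_spec[s], " unreachable for ",
             catalog$name[mi], call. = FALSE)
      }
      site <- .site_with_defects(mirna, defects)
      L <- nchar(site)
      pos <- sample.int(transcript_len - L, 1L)   # 0-based site start
      g <- names(tx)[s]
      tx[[s]] <- paste0(substr(tx[[s]], 1L, pos), site,
                        substr(tx[[s]], pos + L + 1L, transcript_len))
      stopifnot(score_duplex(mirna, site)$total == score_spec[s])
      truth[[length(truth) + 1L]] <- data.frame(
        mirna = catalog$name[mi], gene = g, start = pos, end = pos + L,
        total = score_spec[s])
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(transcripts = tx, truth = truth)
  })
}

#' Simulate a random gene-term annotation
#'
#' @param genes character vector of gene ids.
#' @param n_terms number of distinct terms.
#' @param mean_terms mean terms per gene (Poisson, at least 1).
#' @param seed RNG seed.
#' @return an annotation list as from [read_annotation()].
#' @export
simulate_annotation <- function(genes, n_terms = 30L, mean_terms = 3,
                                seed = 1L) {
  with_seed(seed, {
    terms <- sprintf("TERM:%04d", seq_len(n_terms))
    g <- lapply(genes, function(gn) {
      k <- max(1L, stats::rpois(1L, mean_terms))
      sample(terms, min(k, n_terms))
    })
    names(g) <- genes
    list(genes = g,
         labels = setNames(paste("synthetic term", seq_len(n_terms)),
                           terms),
         namespace = "GO-like")
  })
}

#' Simulate matched qPCR Ct triplicates for planted fold-changes
#'
#' Target Ct values track `-log2(expression)` around a baseline cycle with
#' Gaussian noise; the reference gene (U4) is condition-independent.
#'
#' @param fold_changes named vector of true CG/AG expression ratios.
#' @param seed RNG seed.
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param base_ct,ref_ct baseline Ct of targets and of the reference.
#' @return data.frame: `mirna`, triplicate columns `ct_target_ag1..3`,
#'   `ct_target_cg1..3`, `ct_ref_ag1..3`, `ct_ref_cg1..3`.
#' @export
simulate_qpcr <- function(fold_changes, seed = 1L, noise_sd = 0.1,
                          base_ct = 25, ref_ct = 18) {
  with_seed(seed, {
    n <- length(fold_changes)
    tri <- function(mu) matrix(rnorm(3L * n, mu, noise_sd), ncol = 3L)
    ta <- tri(base_ct)
    tc <- tri(base_ct - log2(fold_changes))
    ra <- tri(ref_ct)
    rc <- tri(ref_ct)
    d <- data.frame(mirna = names(fold_changes), ta, tc, ra, rc)
    names(d) <- c("mirna",
                  paste0("ct_target_ag", 1:3), paste0("ct_target_cg", 1:3),
                  paste0("ct_ref_ag", 1:3), paste0("ct_ref_cg", 1:3))
    d
  })
}

#' Generate a complete synthetic study
#'
#' Orchestrates the stage generators with substreams of one master seed:
#' genome, planted hairpins, two-condition libraries, transcriptome with
#' planted target sites, annotation and qPCR panel. Defaults are the
#' bundled study conditions (100-kb genome, 20 miRNAs, 50,000 reads per
#' condition, 5% noise, a 4-fold CG upregulation for a quarter of the
#' miRNAs).
#'
#' @param seed master seed.
#' @param n_mirnas number of planted miRNAs.
#' @param genome_len genome length (nt).
#' @param depth reads per condition.
#' @param noise_frac noise-read fraction.
#' @param upregulated_frac fraction of miRNAs given the `effect_fc`
#'   fold-change in CG.
#' @param effect_fc fold-change of the upregulated miRNAs.
#' @param transcript_count transcriptome size.
#' @param score_spec planted target-site penalty totals.
#' @param out_dir optional directory: writes `genome.fa`,
#'   `reads_AG.fq.gz`, `reads_CG.fq.gz`, `transcripts.fa`,
#'   `annotation.tsv` and truth tables.
#' @return list with `genome`, `truth` (hairpin truth), `reads`,
#'   `true_counts`, `fold_changes`, `transcripts`, `target_truth`,
#'   `annotation`, `qpcr`, `seed`.
#' @export
simulate_study <- function(seed = 1L, n_mirnas = 20L, genome_len = 1e5,
                           depth = 50000L, noise_frac = 0.05,
                           upregulated_frac = 0.25, effect_fc = 4,
                           transcript_count = 30L,
                           score_spec = c(0, 0.5, 1, 2, 3, 4, 5, 6),
                           out_dir = NULL) {
  genome <- generate_genome(genome_len, gc = 0.5,
                            seed = substream(seed, "genome"))
  matures <- random_matures(n_mirnas, len = 21L,
                            seed = substream(seed, "matures"))
  planted <- plant_hairpins(genome, matures,
                            seed = substream(seed, "hairpins"))
  n_up <- max(1L, round(n_mirnas * upregulated_frac))
  fc <- rep(1, n_mirnas)
  fc[seq_len(n_up)] <- effect_fc
  names(fc) <- planted$truth$name
  libs <- simulate_reads(planted$truth, depth = depth, fold_changes = fc,
                         noise_frac = noise_frac,
                         seed = substream(seed, "reads"))
  cat_df <- mirna_catalog(data.frame(
    family = planted$truth$name, name = planted$truth$name,
    sequence = planted$truth$sequence, class = "novel"))
  tgt <- plant_target_sites(transcript_count, cat_df,
                            score_spec = score_spec,
                            seed = substream(seed, "targets"))
  ann <- simulate_annotation(names(tgt$transcripts),
                             seed = substream(seed, "annotation"))
  qpcr <- simulate_qpcr(fc, seed = substream(seed, "qpcr"))
  out <- list(genome = planted$genome, truth = planted$truth,
              reads = libs$reads, true_counts = libs$true_counts,
              fold_changes = fc, transcripts = tgt$transcripts,
              target_truth = tgt$truth, annotation = ann, qpcr = qpcr,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(names(out$genome), unname(out$genome),
                file.path(out_dir, "genome.fa"))
    for (cond in c("AG", "CG")) {
      r <- out$reads[[cond]]
      write_fastq(paste0(cond, "_", seq_along(r)), r,
                  path = file.path(out_dir,
                                   paste0("reads_", cond, ".fq.gz")))
    }
    write_fasta(names(out$transcripts), unname(out$transcripts),
                file.path(out_dir, "transcripts.fa"))
    writeLines(vapply(names(ann$genes), function(g) {
      paste0(g, "\t", paste(ann$genes[[g]], collapse = ";"))
    }, ""), file.path(out_dir, "annotation.tsv"))
    write.table(out$truth, file.path(out_dir, "truth_hairpins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$target_truth, file.path(out_dir, "truth_targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
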