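---
title: "Methods: miRNA identification and characterization with mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA identification and characterization with mirseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

## Scope and model

`mirseed` re-implements, as a reusable and fully tested pipeline, the
small-RNA analysis used to identify and characterize microRNAs in the
oleaginous microalga *Coccomyxa subellipsoidea* C-169: read cleaning and
collapsing, conserved-miRNA annotation against a reference mature-miRNA
catalog, novel-miRNA discovery through an eleven-criterion hairpin filter,
family statistics, complementarity penalty-scored target prediction,
expression quantification across two culture conditions (air, `AG`, versus
2% CO~2~, `CG`), qRT-PCR fold-change arithmetic, and hypergeometric term
enrichment. The 124-entry mature-miRNA catalog for C-169 (118 conserved in
73 families plus six novel miRNAs) ships with the package
(`c169_catalog()`) and anchors the catalog-level statistics.

The pipeline operates at desk scale — genomes of up to a few megabases held
in memory, searched exactly — which covers the intended use: small-RNA
libraries against compact algal genomes and synthetic validation data.

## Preprocessing

Reads are 3'-adapter trimmed (default adapter: the Illumina TruSeq
small-RNA 3' adapter, `TGGAATTCTCGGGTGCCAAGG`; minimum terminal overlap
6 nt, exact matching). The insert before the left-most adapter occurrence
is kept; adapter dimers and adapter-free reads are dropped, mirroring the
"3' adaptor sequence & length filter" accounting row of a standard
small-RNA sequencing summary. Retained inserts must be 18–25 nt, free of
`N`, and pass a low-complexity screen (dominant single nucleotide < 80% of
the insert). Ribosomal/transfer/sn/snoRNA removal is implemented as
matching (exact or one mismatch) against a user-supplied contaminant FASTA
rather than a live database screen; the default contaminant set is empty,
which keeps the stage deterministic and testable offline. Base qualities
are parsed and deliberately ignored: the protocol this follows states no
quality rule. Valid reads are collapsed to unique sequences with counts,
ordered by count then lexicographically.

## Mapping

Unique reads are mapped to the genome allowing zero or one substitution,
on both strands, with every hit reported. The search is exact for this
regime (no heuristic seeds or E-values), so results are bit-stable; the
test suite pins it against a brute-force all-positions Hamming scan.
Multi-mapping reads keep all loci; identification later prefers loci whose
windows fold into valid hairpins. Matching against reference mature
miRNAs additionally allows the query to be trimmed or extended by up to 3
nt at each end of the reference (configurable) plus one substitution in
the overlap — the conventional tolerance for isomiR ends; the best
reference is the one with the fewest mismatches, then the smallest total
end shift.

## Folding backend

Candidate precursors are the genomic windows 120 nt on each side of a
mapped read, reverse-complemented for minus-strand hits so the mature
sequence always reads 5'→3'. The bundled folding backend computes the
maximum base-pairing secondary structure (Nussinov dynamic programming;
A:U, G:C and G:U wobble pairs; minimum hairpin loop 3 nt) and, among
structures with the maximal pair count, prefers the one with the largest
total nearest-neighbor stacking bonus. The tie-break matters: maximum
pairing alone is massively degenerate on ~260-nt windows, and the stacked
optimum is the helix-like structure a thermodynamic folder would report,
which keeps planted and genuine hairpins intact inside their windows. The
reported energy is the sum of the stacking contributions of the predicted
structure (all stacking terms are negative; isolated pairs contribute
zero), in kcal/mol. This is a deliberately simple, fully deterministic
energy model — adequate because the downstream filter consumes structure
features and an energy bound, not Turner-exact free energies. A
thermodynamic folder can be plugged in as `fold(seq, backend = f)` where
`f(seq)` returns a dot-bracket structure and an energy; the output is
validated against the same invariants (balanced brackets, complementary
pairs, loop ≥ 3, energy ≤ 0). All bundled tests use the bundled backend so
every number in the test suite is reproducible to the bit.

## Hairpin features and the eleven criteria

The folded window is decomposed into stem-loop units: maximal unbranched
chains of nested base pairs (bulges and internal loops allowed; a
multiloop branch ends the unit). Everything enclosed by the innermost
chain pair — including any sub-hairpins spawned by the loop sequence —
counts as that unit's terminal loop; this matches how precursor hairpins
are described in practice, where small substructure in the loop does not
break the stem. The unit whose stem arms overlap the mature span the most
is measured:

| # | feature | threshold |
|---|---------|-----------|
| 1 | base pairs in the stem | ≥ 16 |
| 2 | nucleotides in one stem bulge | ≤ 12 |
| 3 | folding free energy | ≤ −15 kcal/mol |
| 4 | hairpin loop length | ≤ 200 nt |
| 5 | hairpin length (both arms + terminal loop) | ≥ 50 nt |
| 6 | biased errors in one bulge in the mature region | ≤ 2 |
| 7 | nucleotides in one bulge in the mature region | ≤ 4 |
| 8 | base pairs in the mature region | ≥ 12 |
| 9 | errors in the mature region | ≤ 4 |
| 10 | biased bulges in the mature region | ≤ 2 |
| 11 | percent of mature in stem | ≥ 80% |

Interpretation choices that the criterion list leaves open, fixed here and
config-visible:

* An *error* is an unpaired mature position inside the stem region; mature
  positions falling in the terminal loop are handled by criterion 11
  instead.
* A *biased* bulge or error is one-sided: the unpaired run faces zero
  unpaired nucleotides on the opposing arm. Symmetric internal loops are
  bulges on both sides, neither biased.
* Criterion 5 is read as one constraint on the total hairpin length
  (5' arm + terminal loop + 3' arm ≥ 50 nt), not three separate ones.
* Criterion 6 is the largest number of mature nucleotides inside any
  single biased bulge.

A mature span outside every stem-loop yields a zero-feature report (0% in
stem), never an exception. `evaluate_criteria()` reports each comparison
with its measured value and threshold; the overall verdict is the
conjunction of all eleven, and relaxing any threshold can only turn
failures into passes (a property the suite tests).

## Identification

Reads matching a reference mature miRNA become conserved records named
with the `csl-` species prefix; a record is *confirmed* when some genome
locus puts the read in a stem arm of a folded window (≥ 80% in stem), and
flagged `unconfirmed` otherwise — sequence-only evidence is kept visible
rather than silently promoted. The reference search runs against a single
user-supplied catalog; the provenance of the matched reference is recorded
in the record instead of staging species-specific and general searches,
which would require a live miRNA database. Reads left over after conserved
annotation are novel candidates if seen at least twice (singleton reads are
not credible precursor evidence); each genome locus is folded and filtered,
and passing reads are named `csl-nmiR1`, `csl-nmiR2`, … in order of
descending read count, then sequence — the published novel names only fix
the final numbering, so the ordering rule is this package's own convention.
When several loci pass for one read, the locus passing the most criteria
with strict margin wins, ties to the leftmost; both arms of one hairpin are
the same physical precursor and either is a faithful locus.

Families are parsed from reference names case-insensitively as `miR` plus
the leading integer run (`csl-miR166a-5p-1` → `miR166`); novel miRNAs are
their own family. Family statistics (family count, members, largest
family, singleton fraction, mature-length histogram) reproduce the
published catalog structure from the bundled fixture: 73 conserved
families, miR166 largest with 11 members, 58/73 = 79.45% singletons.

## Target prediction

Sites are scored ungapped against every window of miRNA length on the
sense strand of each transcript: Watson–Crick pair 0, G:U wobble 0.5,
mismatch 1, penalties doubled at miRNA positions 2–13 from the 5' end, and
a site totalling ≤ 4 points is reported. No gap penalty is printed in the
scoring rules this follows, so scoring is ungapped: only what the rules
state is implemented, and gapped duplexes (target bulges) are out of
scope. Per (miRNA, gene) pair the
best site is kept (lowest penalty, then leftmost), and genes targeted by
more than one miRNA carry a multiplicity count. Scoring is pinned against
an independent re-implementation of the arithmetic over all windows.

## Quantification

Sequencing expression uses reads-per-million within each condition library
(the normalization is this package's choice — standard for small-RNA
libraries — as the source analysis names none) and log2 fold-changes with
a pseudocount of 1. qRT-PCR relative expression is the textbook
2^−ΔΔCt^ with ΔCt = mean Ct(target) − mean Ct(reference U4) per condition;
agreement between platforms is summarized as the squared Pearson
correlation of log2 fold-changes. The published R² (0.8258) derives from
the study's own wet-lab measurements and is not reproducible from code;
the package instead validates the arithmetic on matched synthetic panels.

## Enrichment

Term over-representation uses the hypergeometric upper tail (computed in
log space via `stats::phyper`) over annotated genes only: genes without
any term are excluded from both the draw and the background, so the test
is conditional on annotation. Raw p-values carry the significance flags at
0.05 and 0.01 used in the published figures; Benjamini–Hochberg q-values
are emitted alongside but do not drive the flags. The *rich factor* is
k/K — enriched target genes of a term over all background genes of that
term.

## The synthetic-data generator

`simulate_study()` emulates the study design with full ground truth. Its
defaults are the package's fixed study conditions: a 100-kb i.i.d. genome
at GC 0.5, 20 planted 21-nt miRNAs, 50,000 reads per condition, 5%
random-noise reads, a rare (2%) 1-nt 3' end trim as isomiR noise, and a
4-fold CG upregulation for a quarter of the miRNAs — magnitudes chosen
once to resemble a down-scaled small-RNA experiment that runs in seconds.
Precursors are planted as mature + ≥8-nt linker + reverse complement,
written into the genome only after the package's own discovery path
(window → fold → features → criteria) accepts the flanked window, with
linker/locus resampling otherwise, so planted truth is criterion-passing
by construction. Read counts are multinomial per condition; condition
effects reweight the multinomial, which means observed per-miRNA RPM
ratios are compressed by the library-composition factor — the recovery
test therefore contrasts upregulated against flat miRNA groups, where the
compression cancels. Target sites of exactly prescribed penalties (defect
positions chosen to hit each total under the doubling rule) are embedded
one per transcript; above-cutoff specs serve as negative controls. A
single master seed drives named substreams per stage, so any stage
regenerates byte-identically in isolation.

What the generator does not emulate: sequencing errors beyond the end
trim, quality-score structure, 5' isomiRs, repetitive genome content,
expression-dependent ligation bias, and hairpins embedded in transcribed
context. Passing the recovery suite therefore demonstrates correctness of
the pipeline's logic under clean planted truth, not performance on real
libraries.

## Numerical and degenerate-input choices

* Sequences are stored in the DNA alphabet (`U` → `T` on input; `as_rna()`
  for display), because the bundled catalog prints T-containing sequences.
* Internal coordinates are 0-based half-open; GFF3 output is 1-based
  inclusive.
* The folding DP breaks ties deterministically (smallest split first,
  stacked extension preferred), so identical inputs give identical
  structures on every platform.
* Zero-total count vectors normalize to all-zero RPM with a warning rather
  than NaN; zero-variance fold-change vectors make R² an error, not NA.
* An empty catalog file parses to an empty catalog with a warning; an
  empty genome is an error.

## Problem sizes in the bundled suites

The test and acceptance suites run the full study conditions for the
recovery checks (100-kb genome, 20 miRNAs, 2 × 50,000 reads) and smaller
constructions (3–40-kb genomes, thousands of reads) for the per-stage
checks; oracle equivalence checks use sequence lengths where exhaustive
enumeration is feasible (≤ 18 nt for structures, N ≤ 12 for
hypergeometric draws). These sizes are the package's chosen validation
scale: large enough that every stage, including multinomial sampling
bounds, is exercised meaningfully.

## Known limitations

* The bundled energy model is a stacking sum, not a full nearest-neighbor
  free-energy model: energies are comparable within this package (and
  bounded checks against the −15 kcal/mol criterion are conservative for
  stable hairpins) but are not Turner/ViennaRNA values.
* Exact Hamming mapping does not scale past desk-size genomes; no
  BWT/FM-index is provided.
* Multi-mapping attribution is keep-all; no fractional count assignment.
* Enrichment takes annotations as given — no GO-graph propagation.
* The conserved/novel split depends entirely on the supplied reference
  catalog; an impoverished catalog inflates the novel class.
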