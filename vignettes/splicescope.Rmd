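---
title: "splicescope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicescope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind splicescope, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate. The package analyses alternative
splicing from bulk RNA-seq at the level of *junction reads*: reads whose
alignment spans an exon–exon boundary and is therefore split into blocks
separated by an intronic gap. The motivating setting is a two-group design —
for example, epithelial cells treated with an HDAC inhibitor such as
butyrate versus untreated controls, four replicates each — where treatment
shifts both which junctions are used and how often.

## Junction extraction

A junction is recorded for every `N` (skipped region) operation in the CIGAR
of a uniquely mapped record. Coordinates are 1-based and fully closed
throughout the package: `left_end` is the last aligned base of the upstream
block and `right_start` the first aligned base of the downstream block, so
the intron occupies `[left_end + 1, right_start - 1]`. This matches the GTF
convention and the way junction positions are printed in the field's tables;
BED output converts to 0-based half-open coordinates through the single
conversion pair `to_bed0()`/`from_bed0()`, which is property-tested for
round-tripping.

Three rules govern extraction:

* **Overhang** (`min_overhang`, default 8 bases): each gap's flanking blocks
  must carry at least 8 read bases aligned to the reference (`M`/`=`/`X`).
  Short overhangs are where spliced aligners misplace reads; 8 bp is the
  conventional floor. Each gap of a multi-gap read is judged on its own
  flanking blocks — the convention is not fixed by the field, and
  per-gap judgment is the least surprising choice.
* **Uniqueness**: records with `NH > 1` or the secondary-alignment flag are
  excluded, so "junction reads %" is a fraction of uniquely mapped reads.
* **Minimum gap**: gaps shorter than 3 bases are dropped; they cannot carry
  two boundary dinucleotides and are alignment artifacts at read scale.

Records whose CIGAR fails to parse are skipped, counted
(`attr(jt, "n_malformed")`) and reported with a warning rather than an
error: a single corrupt record should not abort a library.

## Motif classification and strand inference

The splice-site motif is determined solely by the genome and the strand. On
the plus strand the donor dinucleotide is `genome[left_end+1 .. left_end+2]`
and the acceptor `genome[right_start-2 .. right_start-1]`; on the minus
strand the same two positions are reverse-complemented and swapped so the
classes are read in transcription orientation. Classes are `GT/AG`
(consensus), `GC/AG` (the common non-consensus form), `AT/AC` (minor
spliceosome) and `other`.

Unstranded libraries leave the junction strand unknown. The classifier then
tries both orientations and keeps the one matching a consensus class, which
simultaneously resolves the strand. If both orientations match (possible but
rare) or neither does, the motif is `other` and the strand stays unknown —
a deliberately conservative tie-break, since asserting a strand without
evidence would propagate into the event callers.

## Count normalization and summaries

Raw junction counts are scaled per sample by
`mean(total mapped reads) / total mapped reads[sample]`, equalizing library
sizes while conserving their sum. The mean (rather than median) library size
is used as the reference constant; with balanced designs of equal-depth
libraries the two are nearly identical, and the mean keeps the conservation
property exact. Raw counts are always retained alongside.

The summary mirrors the standard per-sample/per-group layout: junction reads
as a percentage of mapped reads, and the motif composition over junction
sites passing the support filter (mean normalized count across all samples
of at least `min_mean_support = 3` reads). The per-sample denominator for
the composition is not fixed by convention; splicescope counts a site for a
sample when the site passes the global filter and is detected (raw count
> 0) in that sample. Group rows report mean ± sd over replicates and the
pooled-variance t-test p-value between the two groups.

## Topology of two-segment reads

Chimeric alignments (two aligned segments from one read) are classified into
exactly one of five classes, in this order: *translocation* (different
chromosomes), *inversion* (same chromosome, opposite strands), *scramble*
(same chromosome and strand but the downstream half precedes the upstream
half in read order), *distant* (correct order, gap above the window), and
*consistent* otherwise. The window defaults to 20,000 bases — the
conventional maximum intron size for local events — and is shared with the
fusion caller. Only consistent junctions are trusted for event calling; the
other four classes are how genomic rearrangements and alignment artifacts
present in this data type.

## Event calling

**Exon skipping.** A junction calls a skip in a gene when its donor side
equals the transcription-order end of exon *i* and its acceptor side the
transcription-order start of exon *j* with *j* ≥ *i* + 2; the event lists
exons *i*+1 … *j*−1. Matching is exact (0 bp tolerance) by default because
annotated boundaries are exact integers and slack would create double
counting against adjacent annotation; a `tolerance` parameter exists for
noisy annotations. Adjacent-exon junctions are the annotated splice form and
yield no event. A junction matching two overlapping genes emits one event
per gene, flagged `ambiguous`, leaving the disambiguation to the analyst —
the data cannot decide it.

**Read-through fusions (transcription-induced chimeras).** A junction whose
donor breakpoint falls inside gene A and acceptor breakpoint inside a
different gene B, on the same chromosome and strand, with B downstream of A
in transcription direction and breakpoints at most `window` bases apart,
calls a fusion. Breakpoints need *not* sit on exon boundaries: real
read-through events often join intronic or internal positions, so each
breakpoint is annotated with a code — `B` at an exon's transcription-order
start, `E` at its end, `M` strictly inside an exon, `I` inside the intron
between exons *k* and *k*+1, and `flanking` outside the gene span — plus the
gene's exon total, e.g. `E Exon5 (12)`.

**Filtering.** Events keep their supporting junction's normalized counts.
The support filter (all-sample mean ≥ 3) removes single-library noise. A
group-difference filter (|mean₁ − mean₂| ≥ threshold) exists but is **off by
default**: the conventional cut for "large" differences is inconsistent
across published tables, so the threshold is exposed as a parameter rather
than hard-coded.

## Differential testing

The test is the two-sample pooled-variance Student t-test on normalized
counts, df = n₁ + n₂ − 2. Two properties drove this choice:

* it is computable from group summaries (n, mean, sd) alone, and the
  raw-data and summary routes agree exactly — so published mean ± sd tables
  can be re-tested and reproduce their printed p-values;
* with n = 4 per group, pooling is materially better powered than Welch's
  correction when variances are comparable. Welch's test is available via
  `welch = TRUE`.

Degenerate cases are explicit: both variances zero with equal means gives
t = 0, p = 1; both zero with different means gives a zero pooled SE, so the
result is flagged `degenerate` with p at the smallest positive double rather
than a silent 0. Multiplicity is handled with Benjamini–Hochberg adjustment
(`bh_fdr()`, a thin wrapper over `stats::p.adjust`); the step-up procedure
is the field default for FDR control of event lists.

The t-test assumes approximate normality of replicate means. On
negative-binomial counts with moderate means this holds well enough that the
empirical type-I error at the 0.05 level stays near nominal (the acceptance
suite checks a [0.03, 0.07] band on 1,000 simulated null events at group
mean 20); for strongly skewed, very low counts the test is approximate, and
the support filter is what keeps such events out.

## Percent spliced in

For a skip event, the exclusion isoform is measured by the skip junction and
the inclusion isoform by the transcription-adjacent junctions flanking the
skipped block (donor exon to its successor, predecessor of the acceptor exon
to the acceptor exon). Because the two isoforms offer different numbers of
informative junctions, the estimate is a length-normalized density ratio:

Ψ = (inc/inc_pos) / (inc/inc_pos + exc/exc_pos)

with `inc_pos` the number of inclusion junctions actually observed (1 or 2)
and `exc_pos = 1`. This is a point estimate, not a posterior: Bayesian
isoform mixture machinery (posterior sampling, Bayes factors) is out of
scope. The standard read filter is applied on raw totals: at least one
inclusion read, at least one exclusion read, and more than 10 reads in all.
ΔΨ is the difference of group-level estimates; a |ΔΨ| threshold (0.20 is the
conventional screening value) can be requested but is off by default, in
line with the difference filter above.

RPKM (reads × 10⁹ / (exon model length × total mapped)) and its group-mean
ratio provide expression fold changes; a zero control mean is reported as
"induced from zero" rather than an infinite fold.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the package is built
for, at desk scale:

| parameter | default | meaning |
|---|---|---|
| `n_replicates_per_group` | 4 | two groups, treated/control |
| `read_length` | 49 bp | short-read RNA-seq |
| `min_overhang` | 8 bp | overhang rule |
| `n_genes` | 20 | 4–8 exons each, both strands |
| `exon_len` / `intron_len` | 80–200 / 120–800 bp | compact gene models |
| `baseline_junction_mean` | 20 reads | per annotated junction per replicate |
| `dispersion` | 0.1 | NB overdispersion (0 = Poisson) |
| `background_reads` | 15,000 | sets junction reads at ~12–13% of mapped |
| `motif_mix` | GT/AG .94, GC/AG .03, other .03 | AT/AC fixed at 0 |
| `fusion_window` | 20,000 bp | shared with the callers |

Counts are negative-binomial (variance μ + φμ²) because that is the standard
replicate-noise model for RNA-seq counts; Poisson is the φ → 0 limit. The
planted events echo the magnitudes of published skip and fusion tables
(group means 16 vs 0 and 0.25 vs 11 for skips; 236 vs 165 and 11 vs 4 for
fusions). Splice-site dinucleotides are *written into* the genome per
intron, strand-aware, so each junction's class is forced by construction;
"other" introns get `AA..TT`, which matches no consensus class in either
orientation and therefore also exercises the unknown-strand path.
Inconsistent two-segment pairs are drawn from the configured mix of
scramble/inversion/translocation/distant; half as many consistent pairs are
added so all five topology labels occur in the truth table. Gene layout
alternates strands in blocks of two, keeps fusion-hosting neighbors within
the window, and forces one same-strand pair beyond it so both fusion regimes
exist.

What the generator does **not** emulate: sequencing errors and quality
scores, fragment-length and positional biases, multi-mapping ambiguity,
overlapping gene loci, multi-isoform mixtures beyond two isoforms, and
real library depth. Passing tests therefore demonstrate the correctness of
the coordinate arithmetic, classification rules, callers and statistics —
not robustness to alignment noise or annotation error in real data.

Scale: the simulated libraries are three to four orders of magnitude
smaller than production RNA-seq (tens of thousands of reads rather than
tens of millions) but preserve the per-junction mean structure the
statistics operate on. The test suite runs the full pipeline on 6–20 gene
configurations; the acceptance script uses the 20-gene default with 2,000
background reads and 1,000 simulated null events.

## Numerical and engineering choices

* Determinism: every stochastic step derives from `config$seed` through a
  save/restore RNG wrapper, so identical configs give byte-identical
  output — including the SAM, FASTA, GTF and TSV files.
* Standard formats go through standard parsers: Rsamtools/GenomicAlignments
  for SAM/BAM, Biostrings for FASTA, rtracklayer for GTF. The CIGAR junction
  walk itself is implemented in the package (it *is* the analysis) and is
  checked in the tests against both an independent per-base reconstruction
  and `GenomicAlignments::junctions()`.
* p-values are reported in tables rounded to 4 decimals, matching field
  convention; full precision is kept internally and in q-value computation.
* The pipeline aborts before computation if the output directory is not
  writable, and empty inputs produce empty tables with a warning, not an
  error.

## Known limitations

* The Ψ estimate ignores read-length edge effects and within-isoform
  positional bias; it is a screening statistic, not a quantification.
* Overlapping genes produce duplicated, flagged events rather than a
  resolved assignment.
* The fusion caller only looks within the window on one chromosome and
  strand; distal fusions and inversions are classified as inconsistent
  topology and deliberately not called as events.
* With n = 4 per group the t-test has limited power for small effects;
  the q-values are only as meaningful as the event list entering them.
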