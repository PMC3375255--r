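# Fixture builders shared by the test files. Everything is generated in code.

# A small, fast simulation: fewer genes and background reads, no chimeric
# pairs unless asked for.
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_genes = 8, background_reads = 300,
                   n_inconsistent_pairs = 0)
  args <- utils::modifyList(defaults, list(...))
  # default planted events reference genes up to index 8; scale them back for
  # tinier gene sets
  if (args$n_genes < 8) {
    if (is.null(args$planted_skips))
      args$planted_skips <- list(list(gene = 3L, donor_exon = 1L,
                                      acceptor_exon = 4L,
                                      mean_treated = 16, mean_control = 0))
    if (is.null(args$planted_fusions))
      args$planted_fusions <- list(list(gene_a = 1L, gene_b = 2L,
                                        donor_exon = 2L, acceptor_exon = 2L,
                                        mean_treated = 236,
                                        mean_control = 165))
  }
  do.call(sim_config, args)
}

make_dataset <- function(cfg) {
  ref <- simulate_reference(cfg)
  sim <- simulate_alignments(cfg, ref)
  list(cfg = cfg, ref = ref, sim = sim)
}

# Junction table from in-memory simulated alignments, motifs assigned and
# counts normalized.
dataset_jt <- function(ds, min_overhang = 8) {
  jt <- extract_junctions(
    ds$sim$alignments,
    samples = ds$sim$samples[, c("sample", "group", "total_mapped")],
    min_overhang = min_overhang)
  jt <- classify_motif(jt, ds$ref$genome)
  normalize_counts(jt)
}

truth_keys <- function(sim) {
  tj <- sim$truth$junctions
  paste(tj$chrom, tj$left_end, tj$right_start, sep = ":")
}

# Minimal alignment-table row(s) for hand-built reads.
aln_row <- function(qname, chrom, pos, cigar, flag = 0L, nh = 1L,
                    xo = NA_integer_) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = as.integer(pos),
             mapq = 60L, cigar = cigar, strand = "+", nh = as.integer(nh),
             xo = xo, supplementary = bitwAnd(flag, 2048L) > 0,
             stringsAsFactors = FALSE)
}

# Hand-built junction_table: one row per junction, counts as a matrix.
make_jt <- function(junctions, counts, groups = NULL, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(totals)) totals <- rep(1000L, ncol(counts))
  if (is.null(groups)) groups <- rep(NA_character_, ncol(counts))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  keys <- paste(junctions$chrom, junctions$left_end, junctions$right_start,
                sep = ":")
  rownames(counts) <- keys
  rownames(junctions) <- keys
  if (is.null(junctions$strand)) junctions$strand <- "*"
  if (is.null(junctions$motif)) junctions$motif <- NA_character_
  out <- list(junctions = junctions, counts = counts, norm = NULL,
              samples = data.frame(sample = colnames(counts), group = groups,
                                   total_mapped = totals,
                                   stringsAsFactors = FALSE))
  class(out) <- "junction_table"
  out
}

# Gene-model exon table for one gene with given exon count; exons of width
# `exon_w` separated by introns of width `intron_w`.
make_gene <- function(gene_id, chrom = "chrA", strand = "+", n_exons = 4,
                      start = 1000, exon_w = 100, intron_w = 200) {
  starts <- start + (seq_len(n_exons) - 1) * (exon_w + intron_w)
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = as.integer(starts),
                   end = as.integer(starts + exon_w - 1),
                   stringsAsFactors = FALSE)
  df
}

# transcription-order boundary positions of exon k for a make_gene() table
exon_bounds <- function(g, k) {
  gm <- gene_models(g)
  row <- gm[gm$exon_number == k, ]
  if (row$strand == "+") list(tx_start = row$start, tx_end = row$end)
  else list(tx_start = row$end, tx_end = row$start)
}
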