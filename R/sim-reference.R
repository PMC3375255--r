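#' Generate a toy genome and gene annotation with known splice-site motifs
#'
#' Lays out `n_genes` multi-exon genes along a synthetic chromosome (plus a
#' short gene-free second chromosome used by translocated read halves),
#' alternating strands in blocks of two (+, +, -, -, ...) so that adjacent
#' same-strand gene pairs exist on both strands. One adjacent same-strand pair
#' is forced beyond the fusion window (its intergenic gap is
#' `fusion_window + 10000`) and the rest lie well inside it, so both the
#' in-window and out-of-window fusion regimes are represented. Each intron is
#' assigned a splice-site motif class by sampling `config$motif_mix`, and the
#' corresponding boundary dinucleotides are written into the genome in
#' transcription orientation (GT..AG, GC..AG, AT..AC; "other" introns get
#' AA..TT, which matches no consensus class in either orientation), so
#' strand-aware motif classification recovers the assigned class exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_reference`:
#'   \describe{
#'     \item{genome}{A [Biostrings::DNAStringSet] of the chromosomes.}
#'     \item{annotation}{A [GenomicRanges::GRanges] of exon records carrying
#'       `gene_id`, `transcript_id` and `exon_number` (transcription order),
#'       exportable as GTF via [write_reference()].}
#'     \item{genes}{Exon table (one row per exon) as used by
#'       [gene_models()].}
#'     \item{introns}{One row per annotated intron: genomic bounds, gene,
#'       flanking transcription-order exon numbers, and the assigned motif.}
#'     \item{config}{The input config.}
#'   }
#' @examples
#' ref <- simulate_reference(sim_config(seed = 2, n_genes = 6))
#' ref$introns[1:3, c("chrom", "start", "end", "strand", "motif")]
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_reference_impl(config))
}

simulate_reference_impl <- function(cfg) {
  n <- cfg$n_genes
  strands <- rep(c("+", "+", "-", "-"), length.out = n)

  # adjacent gene pairs that host a planted fusion get a short intergenic gap
  # so the breakpoints stay inside the fusion window whatever the exon draws
  fusion_neighbors <- vapply(cfg$planted_fusions, function(fu) {
    idx <- suppressWarnings(as.integer(gsub("\\D", "", c(fu$gene_a, fu$gene_b))))
    if (anyNA(idx)) return(NA_integer_)
    if (abs(diff(idx)) == 1L) max(idx) else NA_integer_
  }, integer(1))
  fusion_neighbors <- fusion_neighbors[!is.na(fusion_neighbors)]
  # one adjacent same-strand pair is pushed beyond the fusion window; pick the
  # first block-internal pair (same strand under the +,+,-,- layout) that does
  # not carry a planted fusion
  far_candidates <- setdiff(seq(2L, n, by = 2L), fusion_neighbors)
  far_candidates <- far_candidates[far_candidates >= 6L]
  far_pair_after <- if (length(far_candidates)) far_candidates[1] - 1L
                    else NA_integer_

  exon_rows <- list()
  intron_rows <- list()
  cursor <- 1000L
  for (g in seq_len(n)) {
    gap <- sample(2000:8000, 1)
    if (g %in% fusion_neighbors) gap <- sample(1500:3000, 1)
    if (!is.na(far_pair_after) && g == far_pair_after + 1L)
      gap <- cfg$fusion_window + 10000L
    gstart <- cursor + gap
    n_ex <- sample_int(cfg$exons_per_gene, 1)
    elen <- sample_int(cfg$exon_len, n_ex)
    ilen <- sample_int(cfg$intron_len, n_ex - 1)
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- gstart
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + elen[e] - 1L
      if (e < n_ex) pos <- ends[e] + ilen[e] + 1L
    }
    strand <- strands[g]
    # transcription-order exon numbers: genomic order for "+", reversed for "-"
    exnum <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    gene_id <- sprintf("GENE%03d", g)
    exon_rows[[g]] <- data.frame(
      gene_id = gene_id, chrom = "chr1", strand = strand,
      start = starts, end = ends, exon_number = exnum,
      n_exons = n_ex, stringsAsFactors = FALSE)
    if (n_ex > 1) {
      motif <- sample(names(cfg$motif_mix), n_ex - 1, replace = TRUE,
                      prob = cfg$motif_mix)
      # intron k sits between genomic exons k and k+1
      don_ex <- if (strand == "+") seq_len(n_ex - 1) else rev(seq_len(n_ex - 1))
      acc_ex <- if (strand == "+") seq_len(n_ex - 1) + 1L else rev(seq_len(n_ex - 1) + 1L)
      intron_rows[[g]] <- data.frame(
        gene_id = gene_id, chrom = "chr1", strand = strand,
        start = ends[-n_ex] + 1L, end = starts[-1] - 1L,
        donor_exon = don_ex, acceptor_exon = acc_ex,
        motif = motif, stringsAsFactors = FALSE)
    }
    cursor <- ends[n_ex]
  }
  genes <- do.call(rbind, exon_rows)
  introns <- do.call(rbind, c(intron_rows, list(stringsAsFactors = FALSE)))
  rownames(genes) <- rownames(introns) <- NULL

  chr1_len <- cursor + 2000L
  chr2_len <- 5000L
  bases <- c("A", "C", "G", "T")
  seq1 <- sample(bases, chr1_len, replace = TRUE)
  seq2 <- sample(bases, chr2_len, replace = TRUE)

  # write boundary dinucleotides so the motif class is forced by the genome
  di <- motif_dinucleotides()
  for (i in seq_len(nrow(introns))) {
    m <- introns$motif[i]
    s <- introns$start[i]; e <- introns$end[i]
    if (introns$strand[i] == "+") {
      seq1[s:(s + 1)] <- strsplit(di[[m]]["donor"], "")[[1]]
      seq1[(e - 1):e] <- strsplit(di[[m]]["acceptor"], "")[[1]]
    } else {
      seq1[(e - 1):e] <- strsplit(revcomp_chr(di[[m]]["donor"]), "")[[1]]
      seq1[s:(s + 1)] <- strsplit(revcomp_chr(di[[m]]["acceptor"]), "")[[1]]
    }
  }
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(seq1, collapse = ""), chr2 = paste(seq2, collapse = "")))

  # transcription-ordered exons for the minus strand appear in the GTF in
  # genomic order with descending exon_number, as Ensembl writes them
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "exon",
    source = "splicescope_sim",
    gene_id = genes$gene_id,
    transcript_id = paste0(genes$gene_id, ".t1"),
    exon_number = as.character(genes$exon_number))

  out <- list(genome = genome, annotation = gr, genes = genes,
              introns = introns, config = cfg)
  class(out) <- "sim_reference"
  out
}

# donor/acceptor dinucleotides per motif class, transcription orientation;
# "other" is AA..TT: matches no consensus class in either orientation
motif_dinucleotides <- function() {
  list("GT/AG" = c(donor = "GT", acceptor = "AG"),
       "GC/AG" = c(donor = "GC", acceptor = "AG"),
       "AT/AC" = c(donor = "AT", acceptor = "AC"),
       "other" = c(donor = "AA", acceptor = "TT"))
}

#' Write a simulated reference to FASTA and GTF
#'
#' @param ref A [simulate_reference()] result.
#' @param fasta,gtf Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_reference <- function(ref, fasta, gtf) {
  stopifnot(inherits(ref, "sim_reference"))
  Biostrings::writeXStringSet(ref$genome, fasta)
  rtracklayer::export(ref$annotation, gtf, format = "gtf")
  invisible(list(fasta = fasta, gtf = gtf))
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", length(x$genome), "sequences,",
      length(unique(x$genes$gene_id)), "genes,",
      nrow(x$introns), "introns\n")
  invisible(x)
}
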