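#' Simulation configuration for the synthetic splicing dataset
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reference()] and [simulate_alignments()]. The defaults describe a
#' desk-scale two-group RNA-seq splicing experiment: 4 treated + 4 control
#' replicates of 49-bp reads over ~20 multi-exon genes on both strands, with
#' negative-binomial junction counts, a splice-site motif mix of ~94% GT/AG,
#' ~3% GC/AG and ~3% non-consensus (and no AT/AC), planted exon-skipping and
#' adjacent-gene read-through fusion events, and a small admixture of
#' inconsistent two-segment alignments (scramble, inversion, translocation,
#' distant).
#'
#' @param seed Integer seed; every downstream draw is derived from it, so an
#'   identical config reproduces the dataset byte for byte.
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Integer range (length-2 vector) of exons per gene.
#' @param exon_len,intron_len Base-pair ranges (length-2 vectors) for exon and
#'   intron lengths.
#' @param n_replicates_per_group Replicates per group (two groups: "treated",
#'   "control").
#' @param read_length Simulated read length in bases.
#' @param min_overhang Minimum aligned bases on each side of a junction; exon
#'   and intron lengths must be at least twice this so every junction read can
#'   satisfy the rule.
#' @param baseline_junction_mean Expected supporting reads per annotated
#'   (adjacent-exon) junction per replicate.
#' @param dispersion Negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`, so 0 gives Poisson counts.
#' @param background_reads Number of contiguous (non-junction) exonic reads per
#'   replicate; sets the junction-read fraction of the library.
#' @param motif_mix Named proportions over `c("GT/AG", "GC/AG", "AT/AC",
#'   "other")` (missing names = 0) used to assign each intron's splice-site
#'   dinucleotides. Must sum to 1. AT/AC defaults to 0.
#' @param planted_skips List of skip specs, each a list with `gene` (gene
#'   index), `donor_exon`, `acceptor_exon` (transcription-order indices with
#'   `acceptor_exon >= donor_exon + 2`), `mean_treated`, `mean_control`.
#' @param planted_fusions List of fusion specs, each a list with `gene_a`,
#'   `gene_b` (adjacent same-strand gene indices, B downstream of A in
#'   transcription direction), `donor_exon` (internal exon of A),
#'   `acceptor_exon` (exon >= 2 of B), `mean_treated`, `mean_control`.
#' @param n_inconsistent_pairs Two-segment read pairs per replicate drawn from
#'   `inconsistent_mix`.
#' @param inconsistent_mix Named proportions over `c("scramble", "inversion",
#'   "translocation", "distant")`.
#' @param fusion_window Maximum donor-to-acceptor breakpoint distance (bases)
#'   for a read-through fusion; also the "distant" threshold for topology.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 6)
#' cfg$motif_mix
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       exons_per_gene = c(4L, 8L),
                       exon_len = c(80L, 200L),
                       intron_len = c(120L, 800L),
                       n_replicates_per_group = 4L,
                       read_length = 49L,
                       min_overhang = 8L,
                       baseline_junction_mean = 20,
                       dispersion = 0.1,
                       background_reads = 15000L,
                       motif_mix = c("GT/AG" = 0.94, "GC/AG" = 0.03,
                                     "other" = 0.03),
                       planted_skips = default_planted_skips(),
                       planted_fusions = default_planted_fusions(),
                       n_inconsistent_pairs = 40L,
                       inconsistent_mix = c(scramble = 0.25, inversion = 0.25,
                                            translocation = 0.25,
                                            distant = 0.25),
                       fusion_window = 20000L) {
  motifs <- c("GT/AG", "GC/AG", "AT/AC", "other")
  mm <- setNames(numeric(4), motifs)
  mm[names(motif_mix)] <- motif_mix
  if (!all(names(motif_mix) %in% motifs))
    stop("motif_mix names must be among: ", paste(motifs, collapse = ", "))
  if (abs(sum(mm) - 1) > 1e-8)
    stop("motif_mix must sum to 1 (got ", sum(mm), ")")
  topo <- c("scramble", "inversion", "translocation", "distant")
  im <- setNames(numeric(4), topo)
  if (length(inconsistent_mix)) {
    if (!all(names(inconsistent_mix) %in% topo))
      stop("inconsistent_mix names must be among: ",
           paste(topo, collapse = ", "))
    im[names(inconsistent_mix)] <- inconsistent_mix
    if (sum(im) > 0) im <- im / sum(im)
  }
  stopifnot(length(exons_per_gene) == 2, length(exon_len) == 2,
            length(intron_len) == 2)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_replicates_per_group < 1)
    stop("n_replicates_per_group must be >= 1")
  if (exon_len[1] < 2 * min_overhang)
    stop("infeasible config: minimum exon length ", exon_len[1],
         " is shorter than 2 * min_overhang = ", 2 * min_overhang,
         "; junction reads could not satisfy the overhang rule")
  if (intron_len[1] < 4)
    stop("infeasible config: introns need >= 4 bases for two boundary ",
         "dinucleotides")
  if (read_length < 2 * min_overhang)
    stop("infeasible config: read_length ", read_length,
         " cannot carry ", min_overhang, "-base overhangs on both sides")
  if (dispersion < 0) stop("dispersion must be >= 0")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_replicates_per_group = as.integer(n_replicates_per_group),
              read_length = as.integer(read_length),
              min_overhang = as.integer(min_overhang),
              baseline_junction_mean = baseline_junction_mean,
              dispersion = dispersion,
              background_reads = as.integer(background_reads),
              motif_mix = mm,
              planted_skips = planted_skips,
              planted_fusions = planted_fusions,
              n_inconsistent_pairs = as.integer(n_inconsistent_pairs),
              inconsistent_mix = im,
              fusion_window = as.integer(fusion_window))
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted exon-skipping events
#'
#' Two skip events echoing the magnitudes seen in differentially regulated
#' skipping: one induced in the treated group (mean 16 vs 0, skipping two
#' exons) and one repressed (mean 0.25 vs 11, skipping one exon).
#' @return List of skip specs (see [sim_config()]).
#' @export
default_planted_skips <- function() {
  list(
    list(gene = 3L, donor_exon = 1L, acceptor_exon = 4L,
         mean_treated = 16, mean_control = 0),
    list(gene = 7L, donor_exon = 2L, acceptor_exon = 4L,
         mean_treated = 0.25, mean_control = 11)
  )
}

#' Default planted read-through fusion events
#'
#' Two adjacent-gene fusions: a high-count event (means 236 vs 165) on a
#' plus-strand gene pair and a lower-count event (11 vs 4) on a minus-strand
#' pair. Gene indices refer to the deterministic layout of
#' [simulate_reference()], which alternates strands in blocks of two
#' (+, +, -, -, ...), so genes 1-2 share "+" and genes 7-8 share "-".
#' @return List of fusion specs (see [sim_config()]).
#' @export
default_planted_fusions <- function() {
  list(
    list(gene_a = 1L, gene_b = 2L, donor_exon = 2L, acceptor_exon = 2L,
         mean_treated = 236, mean_control = 165),
    list(gene_a = 8L, gene_b = 7L, donor_exon = 2L, acceptor_exon = 2L,
         mean_treated = 11, mean_control = 4)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      x$n_replicates_per_group, "+", x$n_replicates_per_group,
      "replicates,", x$read_length, "bp reads, seed", x$seed, "\n")
  cat("  motif mix:",
      paste(sprintf("%s=%.2f", names(x$motif_mix), x$motif_mix),
            collapse = " "), "\n")
  cat("  planted:", length(x$planted_skips), "skips,",
      length(x$planted_fusions), "fusions,",
      x$n_inconsistent_pairs, "inconsistent pairs/replicate\n")
  invisible(x)
}
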