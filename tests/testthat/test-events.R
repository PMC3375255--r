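pair_row <- function(chrom1, strand1, start1, end1,
                     chrom2, strand2, start2, end2) {
  data.frame(chrom1 = chrom1, strand1 = strand1, start1 = start1, end1 = end1,
             chrom2 = chrom2, strand2 = strand2, start2 = start2, end2 = end2,
             stringsAsFactors = FALSE)
}

test_that("topology classes follow the chromosome/strand/order/window rules", {
  p <- rbind(
    pair_row("chr2", "+", 100, 124, "chr5", "+", 500, 524),    # translocation
    pair_row("chr1", "+", 100, 124, "chr1", "-", 500, 524),    # inversion
    pair_row("chr1", "+", 1000, 1024, "chr1", "+", 500, 524),  # scramble
    pair_row("chr1", "+", 100, 124, "chr1", "+", 124 + 3434, 3600), # gap 3433
    pair_row("chr1", "+", 100, 124, "chr1", "+", 124 + 25001, 25300), # 25000
    pair_row("chr1", "-", 5000, 5024, "chr1", "-", 100, 124),  # "-" correct
    pair_row("chr1", "-", 100, 124, "chr1", "-", 5000, 5024))  # "-" scramble
  expect_equal(classify_topology(p, window = 20000),
               c("translocation", "inversion", "scramble", "consistent",
                 "distant", "consistent", "scramble"))
})

test_that("simulated read-half pairs get exactly one label, the planted one", {
  cfg <- small_sim_config(seed = 19, n_genes = 20,
                          n_inconsistent_pairs = 40, background_reads = 0)
  ds <- make_dataset(cfg)
  all_lab <- c("consistent", "scramble", "inversion", "translocation",
               "distant")
  for (s in ds$sim$samples$sample[c(1, 5)]) {
    pairs <- read_half_pairs(ds$sim$alignments[[s]])
    lab <- classify_topology(pairs, window = cfg$fusion_window)
    expect_true(all(lab %in% all_lab))     # exactly one label each
    truth <- ds$sim$truth$pairs
    truth <- truth[truth$sample == s, ]
    expect_identical(lab[match(truth$qname, pairs$qname)], truth$label)
    expect_setequal(unique(truth$label), unique(lab))
  }
})

test_that("exon skipping requires non-adjacent boundary-exact junctions", {
  g <- make_gene("G1", n_exons = 4)
  e1 <- exon_bounds(g, 1); e2 <- exon_bounds(g, 2); e3 <- exon_bounds(g, 3)
  mk <- function(left, right)
    make_jt(data.frame(chrom = "chrA", left_end = left, right_start = right),
            matrix(5, 1, 2))
  ev <- detect_exon_skipping(mk(e1$tx_end, e3$tx_start), g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$skipped_exons, "2")
  expect_equal(ev$donor_exon, 1)
  expect_equal(ev$acceptor_exon, 3)
  # adjacent-exon junction: the annotated splice form, no event
  expect_equal(nrow(detect_exon_skipping(mk(e1$tx_end, e2$tx_start), g)), 0)
  # off-by-one donor: exact matching finds nothing, tolerance 1 recovers it
  off <- mk(e1$tx_end + 1L, e3$tx_start)
  expect_equal(nrow(detect_exon_skipping(off, g)), 0)
  expect_equal(nrow(detect_exon_skipping(off, g, tolerance = 1)), 1)
})

test_that("a 69-exon gene skipping exons 9 and 10 is called from E8 to E11", {
  g <- make_gene("COL5A3like", n_exons = 69)
  e8 <- exon_bounds(g, 8); e11 <- exon_bounds(g, 11)
  jt <- make_jt(data.frame(chrom = "chrA", left_end = e8$tx_end,
                           right_start = e11$tx_start), matrix(16, 1, 2))
  ev <- detect_exon_skipping(jt, g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$skipped_exons, "9,10")
  expect_equal(ev$n_exons_donor, 69)
})

test_that("minus-strand skipping uses transcription-order exon numbers", {
  g <- make_gene("GM", strand = "-", n_exons = 5)
  e2 <- exon_bounds(g, 2); e4 <- exon_bounds(g, 4)
  # transcription runs right to left: donor end of exon 2 is genomically
  # right of the acceptor start of exon 4
  jt <- make_jt(data.frame(chrom = "chrA", left_end = e4$tx_start,
                           right_start = e2$tx_end), matrix(5, 1, 2))
  ev <- detect_exon_skipping(jt, g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$strand, "-")
  expect_equal(ev$donor_exon, 2)
  expect_equal(ev$acceptor_exon, 4)
  expect_equal(ev$skipped_exons, "3")
})

test_that("overlapping gene models emit per-gene events flagged ambiguous", {
  g <- rbind(make_gene("GA", n_exons = 4),
             make_gene("GB", n_exons = 4))   # identical exon structures
  e1 <- exon_bounds(make_gene("GA", n_exons = 4), 1)
  e3 <- exon_bounds(make_gene("GA", n_exons = 4), 3)
  jt <- make_jt(data.frame(chrom = "chrA", left_end = e1$tx_end,
                           right_start = e3$tx_start), matrix(5, 1, 2))
  ev <- detect_exon_skipping(jt, g)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$gene_id, c("GA", "GB"))
  expect_true(all(ev$ambiguous))
})

test_that("fusions join adjacent same-strand genes within the window", {
  gA <- make_gene("KRT8like", n_exons = 12, start = 1000)
  gapped_start <- max(gA$end) + 3000
  gB <- make_gene("KRT4like", n_exons = 9, start = gapped_start)
  genes <- rbind(gA, gB)
  e5 <- exon_bounds(gA, 5)
  b3 <- exon_bounds(gB, 3)
  jt <- make_jt(data.frame(chrom = "chrA", left_end = e5$tx_end,
                           right_start = b3$tx_start), matrix(200, 1, 2))
  ev <- detect_fusions(jt, genes)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gene_id, "KRT8like")
  expect_equal(ev$gene_id2, "KRT4like")
  expect_equal(ev$donor_label, "E Exon5 (12)")
  expect_equal(ev$acceptor_label, "B Exon3 (9)")
  # opposite strands: no fusion
  genes_op <- genes
  genes_op$strand[genes_op$gene_id == "KRT4like"] <- "-"
  expect_equal(nrow(detect_fusions(jt, genes_op)), 0)
  # breakpoints beyond the window: no fusion, and widening restores it
  gC <- make_gene("FAR", n_exons = 9, start = max(gA$end) + 25000)
  genes_far <- rbind(gA, gC)
  c3 <- exon_bounds(gC, 3)
  jt_far <- make_jt(data.frame(chrom = "chrA", left_end = e5$tx_end,
                               right_start = c3$tx_start), matrix(5, 1, 2))
  expect_equal(nrow(detect_fusions(jt_far, genes_far, window = 20000)), 0)
  expect_equal(nrow(detect_fusions(jt_far, genes_far, window = 40000)), 1)
})

test_that("widening the window never removes a fusion call", {
  ds <- make_dataset(small_sim_config(seed = 29, n_genes = 12))
  jt <- dataset_jt(ds)
  genes <- gene_models(ds$ref$annotation)
  w1 <- detect_fusions(jt, genes, window = 20000)
  w2 <- detect_fusions(jt, genes, window = 60000)
  expect_true(all(w1$junction_key %in% w2$junction_key))
})

test_that("breakpoints are coded B/E/M/I/flanking in transcription order", {
  g <- make_gene("G1", n_exons = 5)           # exons 100 wide, introns 200
  gm <- gene_models(g)
  e3 <- gm[gm$exon_number == 3, ]
  expect_equal(annotate_breakpoint(e3$start, gm)$label, "B Exon3 (5)")
  expect_equal(annotate_breakpoint(e3$end, gm)$label, "E Exon3 (5)")
  expect_equal(annotate_breakpoint(e3$start + 10, gm)$code, "M")
  bp <- annotate_breakpoint(e3$end + 50, gm)   # inside intron 3..4
  expect_equal(bp$label, "I Exon3-Exon4 (5)")
  expect_equal(c(bp$exon_a, bp$exon_b), c(3, 4))
  expect_equal(annotate_breakpoint(10, gm)$code, "flanking")
  # minus strand: transcription-order start of exon k is its genomic end
  gmm <- gene_models(make_gene("GM", strand = "-", n_exons = 5))
  e2m <- gmm[gmm$exon_number == 2, ]
  expect_equal(annotate_breakpoint(e2m$end, gmm)$label, "B Exon2 (5)")
  expect_equal(annotate_breakpoint(e2m$start, gmm)$label, "E Exon2 (5)")
  im <- annotate_breakpoint(e2m$start - 50, gmm)  # intron between exons 2, 3
  expect_equal(im$label, "I Exon2-Exon3 (5)")
  # single-exon gene: anything strictly inside is M Exon1
  g1 <- gene_models(make_gene("S", n_exons = 1))
  expect_equal(annotate_breakpoint(g1$start + 5, g1)$label, "M Exon1 (1)")
})

test_that("event filters act on mean support and group difference", {
  j <- data.frame(chrom = "chrA",
                  left_end = c(100L, 400L), right_start = c(300L, 700L))
  counts <- rbind(c(16, 16, 16, 16, 0, 0, 0, 0),     # means 16 vs 0
                  c(3, 3, 3, 3, 2.6, 2.6, 2.6, 2.6)) # all-sample mean 2.8
  jt <- make_jt(j, counts, groups = rep(c("t", "c"), each = 4))
  ev <- rbind(
    data.frame(kind = "exon_skipping", gene_id = "G", gene_id2 = NA,
               chrom = "chrA", strand = "+", donor_exon = 1L,
               acceptor_exon = 3L, n_exons_donor = 4L,
               n_exons_acceptor = 4L, skipped_exons = "2",
               donor_code = "E", acceptor_code = "B",
               donor_label = "E Exon1 (4)", acceptor_label = "B Exon3 (4)",
               left_end = 100L, right_start = 300L,
               junction_key = "chrA:100:300", ambiguous = FALSE),
    data.frame(kind = "exon_skipping", gene_id = "G", gene_id2 = NA,
               chrom = "chrA", strand = "+", donor_exon = 1L,
               acceptor_exon = 3L, n_exons_donor = 4L,
               n_exons_acceptor = 4L, skipped_exons = "2",
               donor_code = "E", acceptor_code = "B",
               donor_label = "E Exon1 (4)", acceptor_label = "B Exon3 (4)",
               left_end = 400L, right_start = 700L,
               junction_key = "chrA:400:700", ambiguous = FALSE))
  class(ev) <- c("splice_events", "data.frame")
  expect_equal(nrow(filter_events(ev, jt, min_mean_support = 3)), 1)
  # difference 16: kept at min_group_diff 10, removed at 20
  expect_equal(nrow(filter_events(ev, jt, min_mean_support = 3,
                                  min_group_diff = 10)), 1)
  expect_equal(nrow(filter_events(ev, jt, min_mean_support = 3,
                                  min_group_diff = 20)), 0)
  # unset difference filter is the identity on the support-passing set
  expect_identical(filter_events(ev, jt, min_mean_support = 0)$junction_key,
                   ev$junction_key)
})

test_that("noise-free simulation gives perfect precision and recall", {
  cfg <- small_sim_config(seed = 37, n_genes = 12)
  ds <- make_dataset(cfg)
  jt <- dataset_jt(ds)
  genes <- gene_models(ds$ref$annotation)
  sk <- filter_events(detect_exon_skipping(jt, genes), jt)
  fu <- filter_events(detect_fusions(jt, genes), jt)
  truth <- ds$sim$truth$events
  tsk <- truth[truth$type == "skip", ]
  tfu <- truth[truth$type == "fusion", ]
  expect_setequal(paste(sk$gene_id, sk$donor_exon, sk$acceptor_exon),
                  paste(tsk$gene_a, tsk$donor_exon, tsk$acceptor_exon))
  expect_setequal(paste(fu$gene_id, fu$gene_id2),
                  paste(tfu$gene_a, tfu$gene_b))
})
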