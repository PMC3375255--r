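test_that("junction coordinates follow from the CIGAR blocks", {
  p <- 5000L
  jt <- extract_junctions(list(s1 = aln_row("r1", "chr1", p, "10M100N10M")))
  expect_equal(nrow(jt$junctions), 1)
  expect_equal(jt$junctions$left_end, p + 9L)
  expect_equal(jt$junctions$right_start, p + 110L)
  ora <- oracle_junctions(p, "10M100N10M")
  expect_equal(jt$junctions$left_end, ora$left_end)
  expect_equal(jt$junctions$right_start, ora$right_start)
})

test_that("the overhang rule drops short flanks and is monotone", {
  a <- rbind(aln_row("r1", "chr1", 100, "5M100N45M"),
             aln_row("r2", "chr1", 100, "8M100N41M"))
  jt <- extract_junctions(list(s1 = a), min_overhang = 8)
  expect_equal(nrow(jt$junctions), 1)         # r1 dropped: 5 < 8
  expect_equal(unname(jt$counts[1, 1]), 1)
  # raising the overhang never adds junctions or counts
  prev <- Inf
  for (oh in c(5, 8, 10, 42)) {
    n <- sum(extract_junctions(list(s1 = a), min_overhang = oh)$counts)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("support adds per sample and multi-gap reads count each junction", {
  a <- rbind(aln_row("r1", "chr1", 100, "10M50N10M"),
             aln_row("r2", "chr1", 100, "10M50N10M"),
             aln_row("r3", "chr1", 500, "20M30N15M50N8M"))
  jt <- extract_junctions(list(s1 = a))
  expect_equal(nrow(jt$junctions), 3)
  dup <- jt$counts[paste("chr1", 109, 160, sep = ":"), 1]
  expect_equal(unname(dup), 2)
  # the two-gap read's junctions match the per-base oracle
  ora <- oracle_junctions(500, "20M30N15M50N8M")
  for (k in 1:2)
    expect_true(paste("chr1", ora$left_end[k], ora$right_start[k],
                      sep = ":") %in% rownames(jt$junctions))
  # each gap is judged on its own flanking blocks: at overhang 10 the first
  # gap of r3 (flanks 20/15) survives, the second (15/8) does not
  jt10 <- extract_junctions(list(s1 = a), min_overhang = 10)
  expect_true(paste("chr1", ora$left_end[1], ora$right_start[1],
                    sep = ":") %in% rownames(jt10$junctions))
  expect_false(paste("chr1", ora$left_end[2], ora$right_start[2],
                     sep = ":") %in% rownames(jt10$junctions))
})

test_that("multi-mapped and malformed records are skipped", {
  a <- rbind(aln_row("r1", "chr1", 100, "10M50N10M"),
             aln_row("r2", "chr1", 100, "10M50N10M", nh = 3L),
             aln_row("r3", "chr1", 100, "10M50N10M", flag = 256L),
             aln_row("r4", "chr1", 100, "10MN10M"))
  expect_warning(jt <- extract_junctions(list(s1 = a)), "malformed")
  expect_equal(unname(jt$counts[1, 1]), 1)
  expect_equal(attr(jt, "n_malformed"), 1L)
})

test_that("motif classes are read strand-aware from the genome", {
  g <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("A", 100), "GT", strrep("C", 46), "AG",
                  strrep("A", 100))))
  # + strand: intron 101..150, GT..AG
  plus <- data.frame(chrom = "chrA", left_end = 100L, right_start = 151L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_motif(plus, g)$motif, "GT/AG")
  # same genome read on the minus strand is CT..AC: not a consensus class
  minus <- plus; minus$strand <- "-"
  expect_equal(classify_motif(minus, g)$motif, "other")
  # a genomically CT..AC intron is GT/AG on the minus strand
  g2 <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("A", 100), "CT", strrep("C", 46), "AC",
                  strrep("A", 100))))
  expect_equal(classify_motif(minus, g2)$motif, "GT/AG")
  # GC/AG donor variant
  g3 <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("A", 100), "GC", strrep("C", 46), "AG",
                  strrep("A", 100))))
  expect_equal(classify_motif(plus, g3)$motif, "GC/AG")
  # unknown strand resolves to the consensus-matching orientation
  unk <- plus; unk$strand <- "*"
  r <- classify_motif(unk, g2)
  expect_equal(r$motif, "GT/AG")
  expect_equal(r$strand, "-")
  # out-of-bounds junction names itself in the error
  bad <- plus; bad$right_start <- 500L
  expect_error(classify_motif(bad, g), "chrA:100-500")
})

test_that("motif classes survive reverse-complementing the genome", {
  ds <- make_dataset(small_sim_config(seed = 17))
  jt <- dataset_jt(ds)
  L <- length(ds$ref$genome[["chr1"]])
  flipped <- Biostrings::DNAStringSet(c(
    chr1 = as.character(Biostrings::reverseComplement(
      ds$ref$genome[["chr1"]]))))
  j2 <- jt$junctions
  j2$left_end <- L - jt$junctions$right_start + 1L
  j2$right_start <- L - jt$junctions$left_end + 1L
  j2$strand <- chartr("+-", "-+", jt$junctions$strand)
  r <- classify_motif(j2[, c("chrom", "left_end", "right_start", "strand")],
                      flipped)
  expect_identical(r$motif, jt$junctions$motif)
})

test_that("normalization rescales by mean library size", {
  j <- data.frame(chrom = "chr1", left_end = 100L, right_start = 200L)
  jt <- make_jt(j, matrix(c(10, 10), 1), totals = c(50, 100))
  jt <- normalize_counts(jt)
  expect_equal(unname(jt$norm[1, ]), c(15, 7.5))
  # equal totals leave counts unchanged
  jte <- make_jt(j, matrix(c(10, 10), 1), totals = c(80, 80))
  expect_equal(unname(normalize_counts(jte)$norm[1, ]), c(10, 10))
  jt0 <- make_jt(j, matrix(c(10, 10), 1), totals = c(0, 100))
  expect_error(normalize_counts(jt0), "zero total")
})

test_that("summaries partition motifs and apply the mean-support filter", {
  j <- data.frame(chrom = "chr1",
                  left_end = c(100L, 400L),
                  right_start = c(200L, 600L))
  counts <- rbind(rep(1, 8), c(5, 5, 5, 5, 1, 1, 1, 1))
  jt <- make_jt(j, counts, groups = rep(c("t", "c"), each = 4),
                totals = rep(1000L, 8))
  jt$junctions$motif <- c("GT/AG", "GC/AG")
  jt$junctions$strand <- "+"
  s <- summarize_junctions(jt, min_mean_support = 3)
  expect_equal(s$n_supported, 1)   # mean 1 removed, mean 3 kept
  pct <- as.matrix(s$per_sample[, paste0("pct_", c("GT/AG", "GC/AG",
                                                   "AT/AC", "other"))])
  expect_equal(unname(rowSums(pct)), rep(100, 8))
  # only the kept junction (GC/AG) contributes to the composition
  expect_equal(unname(s$per_sample[["pct_GC/AG"]]), rep(100, 8))
  expect_equal(s$per_group$p_value[s$per_group$metric == "total_mapped"], 1)
})

test_that("per-sample junction percentages use the mapped-read totals", {
  ds <- make_dataset(small_sim_config(seed = 23, background_reads = 1000))
  jt <- dataset_jt(ds)
  jt <- classify_motif(jt, ds$ref$genome)
  s <- summarize_junctions(jt)
  expected <- 100 * colSums(jt$counts) / ds$sim$samples$total_mapped
  expect_equal(s$per_sample$junction_reads_pct, unname(expected))
})

test_that("junction coordinates agree with GenomicAlignments::junctions", {
  ds <- make_dataset(small_sim_config(seed = 61, n_genes = 6))
  a <- ds$sim$alignments$treated_1
  a <- a[grepl("N", a$cigar, fixed = TRUE), ]
  jt <- extract_junctions(list(x = a), min_overhang = 0)
  gal <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(a$chrom)),
    pos = a$pos, cigar = a$cigar,
    strand = S4Vectors::Rle(GenomicRanges::strand(rep("+", nrow(a)))))
  introns <- unlist(GenomicAlignments::junctions(gal))
  ref_keys <- paste(GenomicRanges::seqnames(introns),
                    GenomicRanges::start(introns) - 1L,
                    GenomicRanges::end(introns) + 1L, sep = ":")
  expect_setequal(rownames(jt$junctions), unique(ref_keys))
  tab <- table(ref_keys)
  expect_equal(unname(jt$counts[names(tab), 1]), unname(as.integer(tab)))
})
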