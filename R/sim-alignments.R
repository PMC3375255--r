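#' Simulate per-replicate spliced and chimeric alignments with known truth
#'
#' Generates, for each replicate of the two groups, gapped junction reads over
#' every annotated adjacent-exon junction plus the planted exon-skipping and
#' read-through fusion junctions, contiguous background (non-junction) exonic
#' reads, and two-segment read-half pairs of planted topology (consistent,
#' scramble, inversion, translocation, distant). Supporting read counts per
#' junction per replicate are drawn from a negative binomial with the group's
#' mean and `config$dispersion` (Poisson when dispersion is 0). Each junction
#' read is a single-gap record whose two aligned blocks flank the intron with
#' overhangs of at least `config$min_overhang` bases on both sides.
#'
#' @param config A [sim_config()] object (the same one used for the
#'   reference).
#' @param ref The matching [simulate_reference()] result.
#' @return A list of class `sim_alignments`:
#'   \describe{
#'     \item{alignments}{Named list (one per sample) of canonical alignment
#'       tables (see [read_alignments()]).}
#'     \item{samples}{data.frame with `sample`, `group`, `total_mapped`.}
#'     \item{truth}{List with `junctions` (one row per planted junction:
#'       coordinates, motif class, type adjacent/skip/fusion, flanking exon
#'       numbers, group means), `counts` (realized junction-by-sample count
#'       matrix), `events` (the planted skip/fusion events) and `pairs`
#'       (per-replicate read-half pairs with their planted topology label).}
#'     \item{seqlengths}{Named chromosome lengths for SAM headers.}
#'   }
#' @examples
#' cfg <- sim_config(seed = 3, n_genes = 8, n_inconsistent_pairs = 0,
#'                   background_reads = 500)
#' ref <- simulate_reference(cfg)
#' sim <- simulate_alignments(cfg, ref)
#' sim$samples
#' @export
simulate_alignments <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"), inherits(ref, "sim_reference"))
  with_seed(config$seed + 1L, simulate_alignments_impl(config, ref))
}

simulate_alignments_impl <- function(cfg, ref) {
  truth_j <- build_truth_junctions(ref)
  k <- cfg$n_replicates_per_group
  samples <- data.frame(
    sample = c(paste0("treated_", seq_len(k)), paste0("control_", seq_len(k))),
    group = rep(c("treated", "control"), each = k),
    stringsAsFactors = FALSE)
  L <- cfg$read_length
  oh <- cfg$min_overhang
  seqlens <- setNames(Biostrings::width(ref$genome), names(ref$genome))

  nj <- nrow(truth_j)
  counts <- matrix(0L, nj, nrow(samples),
                   dimnames = list(truth_j$junction_id, samples$sample))
  aln <- vector("list", nrow(samples))
  names(aln) <- samples$sample
  pair_rows <- list()

  exon_pool <- ref$genes[ref$genes$end - ref$genes$start + 1L >= L, ]
  if (nrow(exon_pool) == 0 && cfg$background_reads > 0)
    stop("no exon long enough to host a ", L, "-bp background read")

  for (s in seq_len(nrow(samples))) {
    grp <- samples$group[s]
    mu <- if (grp == "treated") truth_j$mean_treated else truth_j$mean_control
    cnt <- draw_counts(mu, cfg$dispersion)
    counts[, s] <- cnt

    # junction reads: overhang m on the donor-side block, L - m downstream
    idx <- rep.int(seq_len(nj), cnt)
    m <- sample_int(c(oh, L - oh), length(idx))
    gap <- truth_j$right_start[idx] - truth_j$left_end[idx] - 1L
    jr <- if (length(idx) == 0) NULL else data.frame(
      qname = sprintf("%s_J%06d", samples$sample[s], seq_along(idx)),
      flag = 0L,
      chrom = truth_j$chrom[idx],
      pos = truth_j$left_end[idx] - m + 1L,
      mapq = 60L,
      cigar = sprintf("%dM%dN%dM", m, gap, L - m),
      strand = "+", nh = 1L, xo = NA_integer_,
      supplementary = FALSE, stringsAsFactors = FALSE)

    # contiguous background reads inside exons
    bg <- NULL
    if (cfg$background_reads > 0) {
      bi <- sample.int(nrow(exon_pool), cfg$background_reads, replace = TRUE)
      maxoff <- exon_pool$end[bi] - exon_pool$start[bi] - L + 1L
      off <- floor(runif(length(bi)) * (maxoff + 1))
      bg <- data.frame(
        qname = sprintf("%s_B%06d", samples$sample[s], seq_along(bi)),
        flag = 0L,
        chrom = exon_pool$chrom[bi],
        pos = exon_pool$start[bi] + as.integer(off),
        mapq = 60L,
        cigar = sprintf("%dM", L),
        strand = "+", nh = 1L, xo = NA_integer_,
        supplementary = FALSE, stringsAsFactors = FALSE)
    }

    pr <- simulate_pairs(cfg, samples$sample[s], seqlens)
    aln[[s]] <- rbind(jr, bg, pr$records)
    pair_rows[[s]] <- pr$truth
  }

  pairs <- do.call(rbind, pair_rows)
  samples$total_mapped <- vapply(aln, function(a) length(unique(a$qname)), 0L)

  events <- truth_j[truth_j$type != "adjacent", , drop = FALSE]
  rownames(events) <- NULL
  out <- list(alignments = aln, samples = samples,
              truth = list(junctions = truth_j, counts = counts,
                           events = events, pairs = pairs),
              seqlengths = seqlens, config = cfg)
  class(out) <- "sim_alignments"
  out
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion > 0) {
    out <- integer(n)
    pos <- mu > 0
    out[pos] <- stats::rnbinom(sum(pos), size = 1 / dispersion, mu = mu[pos])
    out
  } else {
    stats::rpois(n, mu)
  }
}

# One row per junction the generator will cover: every adjacent intron at the
# baseline mean, plus the planted skip and fusion junctions at their group
# means. Motif classes for planted events are derived from the dinucleotides
# written into the genome for the introns whose boundaries the event reuses.
build_truth_junctions <- function(ref) {
  cfg <- ref$config
  adj <- data.frame(
    type = "adjacent",
    gene_a = ref$introns$gene_id, gene_b = ref$introns$gene_id,
    chrom = ref$introns$chrom, strand = ref$introns$strand,
    left_end = ref$introns$start - 1L, right_start = ref$introns$end + 1L,
    donor_exon = ref$introns$donor_exon,
    acceptor_exon = ref$introns$acceptor_exon,
    motif = ref$introns$motif,
    mean_treated = cfg$baseline_junction_mean,
    mean_control = cfg$baseline_junction_mean,
    stringsAsFactors = FALSE)
  rows <- list(adj)
  for (sp in cfg$planted_skips) rows <- c(rows, list(skip_truth(ref, sp)))
  for (fu in cfg$planted_fusions) rows <- c(rows, list(fusion_truth(ref, fu)))
  tj <- do.call(rbind, rows)
  tj$junction_id <- sprintf("J%04d", seq_len(nrow(tj)))
  rownames(tj) <- NULL
  tj
}

gene_index_id <- function(g) {
  if (is.numeric(g)) sprintf("GENE%03d", g) else as.character(g)
}

skip_truth <- function(ref, sp) {
  gid <- gene_index_id(sp$gene)
  ex <- ref$genes[ref$genes$gene_id == gid, ]
  if (nrow(ex) == 0) stop("planted skip names unknown gene: ", gid)
  i <- sp$donor_exon; j <- sp$acceptor_exon
  if (j < i + 2) stop("planted skip needs acceptor_exon >= donor_exon + 2")
  if (j > max(ex$exon_number)) stop("planted skip exceeds exon count of ", gid)
  strand <- ex$strand[1]
  d <- ex[ex$exon_number == i, ]
  a <- ex[ex$exon_number == j, ]
  if (strand == "+") { left_end <- d$end; right_start <- a$start }
  else               { left_end <- a$end; right_start <- d$start }
  intr <- ref$introns[ref$introns$gene_id == gid, ]
  di <- motif_dinucleotides()
  donor_di <- di[[intr$motif[intr$donor_exon == i]]]["donor"]
  acc_di <- di[[intr$motif[intr$acceptor_exon == j]]]["acceptor"]
  data.frame(type = "skip", gene_a = gid, gene_b = gid,
             chrom = ex$chrom[1], strand = strand,
             left_end = left_end, right_start = right_start,
             donor_exon = i, acceptor_exon = j,
             motif = classify_dinucleotides(donor_di, acc_di),
             mean_treated = sp$mean_treated, mean_control = sp$mean_control,
             stringsAsFactors = FALSE)
}

fusion_truth <- function(ref, fu) {
  ga <- gene_index_id(fu$gene_a); gb <- gene_index_id(fu$gene_b)
  exa <- ref$genes[ref$genes$gene_id == ga, ]
  exb <- ref$genes[ref$genes$gene_id == gb, ]
  if (nrow(exa) == 0 || nrow(exb) == 0)
    stop("planted fusion names unknown gene(s): ", ga, ", ", gb)
  strand <- exa$strand[1]
  if (strand != exb$strand[1])
    stop("planted fusion genes must share a strand: ", ga, "/", gb)
  e <- fu$donor_exon; b <- fu$acceptor_exon
  if (e >= max(exa$exon_number))
    stop("fusion donor_exon must be internal (an intron must follow it)")
  if (b < 2) stop("fusion acceptor_exon must be >= 2")
  de <- exa[exa$exon_number == e, ]
  ab <- exb[exb$exon_number == b, ]
  if (strand == "+") { donor_pos <- de$end; acceptor_pos <- ab$start }
  else               { donor_pos <- de$start; acceptor_pos <- ab$end }
  dist <- if (strand == "+") acceptor_pos - donor_pos else donor_pos - acceptor_pos
  if (dist <= 0)
    stop("fusion acceptor gene must lie downstream of the donor gene ",
         "in transcription direction: ", ga, " -> ", gb)
  if (dist > ref$config$fusion_window)
    stop("planted fusion breakpoints are ", dist,
         " bp apart, beyond the fusion window of ", ref$config$fusion_window)
  ia <- ref$introns[ref$introns$gene_id == ga, ]
  ib <- ref$introns[ref$introns$gene_id == gb, ]
  di <- motif_dinucleotides()
  donor_di <- di[[ia$motif[ia$donor_exon == e]]]["donor"]
  acc_di <- di[[ib$motif[ib$acceptor_exon == b]]]["acceptor"]
  left_end <- min(donor_pos, acceptor_pos)
  right_start <- max(donor_pos, acceptor_pos)
  data.frame(type = "fusion", gene_a = ga, gene_b = gb,
             chrom = exa$chrom[1], strand = strand,
             left_end = left_end, right_start = right_start,
             donor_exon = e, acceptor_exon = b,
             motif = classify_dinucleotides(donor_di, acc_di),
             mean_treated = fu$mean_treated, mean_control = fu$mean_control,
             stringsAsFactors = FALSE)
}

# Two-segment read-half pairs with a planted topology label. The inconsistent
# classes follow config$inconsistent_mix; half as many consistent pairs are
# added so the "consistent" label is also represented in the truth table.
simulate_pairs <- function(cfg, sample_id, seqlens) {
  n_inc <- cfg$n_inconsistent_pairs
  if (n_inc > 0 && sum(cfg$inconsistent_mix) == 0) n_inc <- 0L
  n_con <- n_inc %/% 2L
  n <- n_inc + n_con
  empty <- list(records = NULL,
                truth = data.frame(sample = character(), qname = character(),
                                   label = character(),
                                   stringsAsFactors = FALSE))
  if (n == 0) return(empty)
  labels <- c(if (n_inc > 0)
                sample(names(cfg$inconsistent_mix), n_inc, replace = TRUE,
                       prob = cfg$inconsistent_mix),
              rep("consistent", n_con))
  L <- cfg$read_length
  l1 <- L %/% 2L; l2 <- L - l1
  chr1_len <- seqlens[["chr1"]]
  w <- cfg$fusion_window
  if (any(labels == "distant") && chr1_len < 2L * w + 20000L)
    stop("chr1 too short to place distant read-half pairs; ",
         "add genes or shrink the fusion window")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    st <- sample(c("+", "-"), 1)
    a <- sample(1000:max(1001L, chr1_len - 2L * w - 15000L), 1)
    h1 <- list(chrom = "chr1", strand = st, start = a, len = l1)
    if (lab == "translocation") {
      h2 <- list(chrom = "chr2", strand = st,
                 start = sample(100:(seqlens[["chr2"]] - l2), 1), len = l2)
    } else if (lab == "inversion") {
      h2 <- list(chrom = "chr1", strand = if (st == "+") "-" else "+",
                 start = a + l1 + sample(200:2000, 1), len = l2)
    } else if (lab == "scramble") {
      # wrong transcription order on the shared strand
      if (st == "+") {
        h1$start <- a + l2 + sample(50:2000, 1)
        h2 <- list(chrom = "chr1", strand = st, start = a, len = l2)
      } else {
        h2 <- list(chrom = "chr1", strand = st,
                   start = a + l1 + sample(50:2000, 1), len = l2)
      }
    } else {
      gap <- if (lab == "distant") w + sample(1000:5000, 1)
             else sample(50:5000, 1)
      if (st == "+") {
        h2 <- list(chrom = "chr1", strand = st, start = a + l1 + gap, len = l2)
      } else {
        h2 <- list(chrom = "chr1", strand = st, start = a, len = l2)
        h1$start <- a + l2 + gap
      }
    }
    qn <- sprintf("%s_P%04d", sample_id, i)
    recs[[i]] <- data.frame(
      qname = qn,
      flag = c(ifelse(h1$strand == "-", 16L, 0L),
               2048L + ifelse(h2$strand == "-", 16L, 0L)),
      chrom = c(h1$chrom, h2$chrom),
      pos = c(h1$start, h2$start),
      mapq = 60L,
      cigar = sprintf("%dM", c(h1$len, h2$len)),
      strand = c(h1$strand, h2$strand),
      nh = 1L, xo = c(1L, 2L),
      supplementary = c(FALSE, TRUE), stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs),
       truth = data.frame(sample = sample_id,
                          qname = sprintf("%s_P%04d", sample_id, seq_len(n)),
                          label = labels, stringsAsFactors = FALSE))
}

#' Write simulated alignments and truth tables to a directory
#'
#' Writes one SAM file per sample, a `samples.tsv` sheet (sample, group,
#' total mapped reads, path), and plain-TSV truth tables
#' (`truth_junctions.tsv`, `truth_events.tsv`, `truth_pairs.tsv`).
#'
#' @param sim A [simulate_alignments()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sample sheet with a `path` column.
#' @export
write_alignments <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_alignments"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$samples
  sheet$path <- file.path(dir, paste0(sheet$sample, ".sam"))
  for (i in seq_len(nrow(sheet)))
    write_sam(sim$alignments[[sheet$sample[i]]], sheet$path[i],
              sim$seqlengths)
  write_tsv <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_tsv(sheet, "samples.tsv")
  write_tsv(sim$truth$junctions, "truth_junctions.tsv")
  write_tsv(sim$truth$events, "truth_events.tsv")
  write_tsv(sim$truth$pairs, "truth_pairs.tsv")
  invisible(sheet)
}

#' @export
print.sim_alignments <- function(x, ...) {
  cat("sim_alignments:", nrow(x$samples), "samples,",
      nrow(x$truth$junctions), "true junctions,",
      nrow(x$truth$events), "planted events\n")
  invisible(x)
}
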