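#' Build gene models from a GTF annotation
#'
#' Collects exon records into the flat exon table used by the event callers:
#' one row per exon with 1-based closed genomic bounds and the exon number in
#' transcription order (exon 1 is the 5'-most exon, i.e. genomically last for
#' minus-strand genes). When a gene has several transcripts the union of
#' identical exon records is kept; exon numbers are recomputed per gene from
#' the strand-aware order, so genes are treated as a single ordered exon
#' chain.
#'
#' @param x Path to a GTF file, a [GenomicRanges::GRanges] of exon records
#'   (with a `gene_id` column), or an exon data.frame with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @return A data.frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `exon_number`, `n_exons`.
#' @export
gene_models <- function(x) {
  if (is.character(x)) x <- rtracklayer::import(x, format = "gtf")
  if (inherits(x, "GRanges")) {
    md <- S4Vectors::mcols(x)
    if (!is.null(md$type)) x <- x[md$type == "exon"]
    md <- S4Vectors::mcols(x)
    if (is.null(md$gene_id)) stop("annotation lacks a gene_id attribute")
    x <- data.frame(gene_id = as.character(md$gene_id),
                    chrom = as.character(GenomicRanges::seqnames(x)),
                    strand = as.character(GenomicRanges::strand(x)),
                    start = GenomicRanges::start(x),
                    end = GenomicRanges::end(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(x)))
  x <- unique(x[, c("gene_id", "chrom", "strand", "start", "end")])
  if (any(!x$strand %in% c("+", "-")))
    stop("gene models need a '+' or '-' strand for every exon")
  x <- x[order(x$gene_id, x$start), , drop = FALSE]
  parts <- split(seq_len(nrow(x)), x$gene_id)
  x$exon_number <- NA_integer_
  x$n_exons <- NA_integer_
  for (idx in parts) {
    n <- length(idx)
    s <- x$strand[idx[1]]
    if (any(x$end[idx][-n] >= x$start[idx][-1][seq_len(n - 1)]))
      stop("overlapping exons within gene ", x$gene_id[idx[1]])
    x$exon_number[idx] <- if (s == "+") seq_len(n) else rev(seq_len(n))
    x$n_exons[idx] <- n
  }
  rownames(x) <- NULL
  class(x) <- c("gene_models", "data.frame")
  x
}

#' Classify the topology of two-segment read alignments
#'
#' Each pair of read halves (two aligned segments from one read, in read
#' order) is assigned exactly one of five labels:
#' \describe{
#'   \item{translocation}{halves on different chromosomes;}
#'   \item{inversion}{same chromosome, opposite strands;}
#'   \item{scramble}{same chromosome and strand but the downstream half
#'     precedes the upstream half in read order;}
#'   \item{distant}{correct order but separated by more than `window` bases;}
#'   \item{consistent}{otherwise.}
#' }
#' Only consistent junctions enter event calling.
#'
#' @param pairs A data.frame with one row per pair: `chrom1`, `strand1`,
#'   `start1`, `end1` (first half in read order) and the same four `2`
#'   columns, as built by [read_half_pairs()].
#' @param window Maximum intervening gap for a consistent pair (default
#'   20000).
#' @return Character vector of labels, one per row.
#' @export
classify_topology <- function(pairs, window = 20000) {
  lab <- character(nrow(pairs))
  diff_chrom <- pairs$chrom1 != pairs$chrom2
  diff_strand <- !diff_chrom & pairs$strand1 != pairs$strand2
  rest <- !diff_chrom & !diff_strand
  plus <- rest & pairs$strand1 == "+"
  correct <- rest & ifelse(pairs$strand1 == "+",
                           pairs$start2 > pairs$end1,
                           pairs$end2 < pairs$start1)
  gap <- ifelse(plus, pairs$start2 - pairs$end1 - 1L,
                pairs$start1 - pairs$end2 - 1L)
  lab[diff_chrom] <- "translocation"
  lab[diff_strand] <- "inversion"
  lab[rest & !correct] <- "scramble"
  lab[rest & correct & gap > window] <- "distant"
  lab[rest & correct & gap <= window] <- "consistent"
  lab
}

#' Pair up two-segment alignment records
#'
#' Collects the two-segment (chimeric) records of an alignment table -- those
#' carrying the half-order tag `XO` -- into one row per read with both halves
#' in read order.
#'
#' @param aln Alignment table (see [read_alignments()]).
#' @return data.frame with `qname`, `chrom1`, `strand1`, `start1`, `end1`,
#'   `chrom2`, `strand2`, `start2`, `end2`.
#' @export
read_half_pairs <- function(aln) {
  a <- aln[!is.na(aln$xo), , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(qname = character(), chrom1 = character(),
                      strand1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      strand2 = character(), start2 = integer(),
                      end2 = integer(), stringsAsFactors = FALSE))
  a$refwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(a$cigar)
  a <- a[order(a$qname, a$xo), , drop = FALSE]
  h1 <- a[a$xo == 1L, , drop = FALSE]
  h2 <- a[a$xo == 2L, , drop = FALSE]
  m <- match(h1$qname, h2$qname)
  keep <- !is.na(m)
  h1 <- h1[keep, , drop = FALSE]
  h2 <- h2[m[keep], , drop = FALSE]
  data.frame(qname = h1$qname,
             chrom1 = h1$chrom, strand1 = h1$strand, start1 = h1$pos,
             end1 = h1$pos + h1$refwidth - 1L,
             chrom2 = h2$chrom, strand2 = h2$strand, start2 = h2$pos,
             end2 = h2$pos + h2$refwidth - 1L,
             stringsAsFactors = FALSE)
}

# transcription-order boundary positions for every exon of a gene_models table
boundary_tables <- function(genes) {
  plus <- genes$strand == "+"
  donors <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                       strand = genes$strand, exon = genes$exon_number,
                       n_exons = genes$n_exons,
                       pos = ifelse(plus, genes$end, genes$start),
                       stringsAsFactors = FALSE)
  acceptors <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          strand = genes$strand, exon = genes$exon_number,
                          n_exons = genes$n_exons,
                          pos = ifelse(plus, genes$start, genes$end),
                          stringsAsFactors = FALSE)
  list(donors = donors, acceptors = acceptors)
}

#' Call exon-skipping events from a junction table
#'
#' A junction calls an exon-skipping event in a gene when its donor side
#' coincides exactly with the transcription-order end of exon i and its
#' acceptor side with the transcription-order start of exon j of the same
#' gene, with `j >= i + 2`; the event lists the skipped exons
#' `i+1 ... j-1`. Adjacent-exon junctions (`j = i + 1`) are the annotated
#' splice form and yield no event. Boundary matching is exact by default; a
#' `tolerance` in bases can be allowed. A junction matching more than one
#' gene (overlapping loci) emits one event per gene, flagged `ambiguous`.
#'
#' @param jt A `junction_table` (motifs/strand need not be assigned; a known
#'   junction strand restricts matching to genes on that strand).
#' @param genes A [gene_models()] table.
#' @param tolerance Maximum boundary mismatch in bases (default 0).
#' @return A data.frame of class `splice_events` (kind `"exon_skipping"`)
#'   with the donor/acceptor exon numbers, skipped exon list, genomic
#'   coordinates, junction key and ambiguity flag.
#' @export
detect_exon_skipping <- function(jt, genes, tolerance = 0) {
  stopifnot(inherits(jt, "junction_table"))
  genes <- as_gene_models(genes)
  bt <- boundary_tables(genes)
  j <- jt$junctions
  rows <- list()
  for (i in seq_len(nrow(j))) {
    for (s in c("+", "-")) {
      if (j$strand[i] %in% c("+", "-") && j$strand[i] != s) next
      dpos <- if (s == "+") j$left_end[i] else j$right_start[i]
      apos <- if (s == "+") j$right_start[i] else j$left_end[i]
      d <- bt$donors[bt$donors$chrom == j$chrom[i] &
                       bt$donors$strand == s &
                       abs(bt$donors$pos - dpos) <= tolerance, , drop = FALSE]
      if (nrow(d) == 0) next
      a <- bt$acceptors[bt$acceptors$chrom == j$chrom[i] &
                          bt$acceptors$strand == s &
                          abs(bt$acceptors$pos - apos) <= tolerance, ,
                        drop = FALSE]
      if (nrow(a) == 0) next
      hits <- merge(d, a, by = c("gene_id", "chrom", "strand", "n_exons"),
                    suffixes = c("_donor", "_acceptor"))
      hits <- hits[hits$exon_acceptor >= hits$exon_donor + 2L, , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        skipped <- seq(hits$exon_donor[h] + 1L, hits$exon_acceptor[h] - 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "exon_skipping",
          gene_id = hits$gene_id[h], gene_id2 = NA_character_,
          chrom = j$chrom[i], strand = s,
          donor_exon = hits$exon_donor[h],
          acceptor_exon = hits$exon_acceptor[h],
          n_exons_donor = hits$n_exons[h], n_exons_acceptor = hits$n_exons[h],
          skipped_exons = paste(skipped, collapse = ","),
          donor_code = "E", acceptor_code = "B",
          donor_label = sprintf("E Exon%d (%d)", hits$exon_donor[h],
                                hits$n_exons[h]),
          acceptor_label = sprintf("B Exon%d (%d)", hits$exon_acceptor[h],
                                   hits$n_exons[h]),
          left_end = j$left_end[i], right_start = j$right_start[i],
          junction_key = rownames(j)[i],
          ambiguous = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  ev <- rbind_events(rows)
  flag_ambiguous(ev)
}

#' Call local read-through gene fusions (transcription-induced chimeras)
#'
#' A junction calls a fusion when its donor breakpoint falls inside one gene
#' and its acceptor breakpoint inside a different gene on the same chromosome
#' and strand, the acceptor gene lying downstream of the donor gene in
#' transcription direction, with the two breakpoints at most `window` bases
#' apart. Breakpoints need not sit on exon boundaries: each is annotated with
#' [annotate_breakpoint()] codes (B = exon start, E = exon end, M = inside an
#' exon, I = inside an intron, in transcription order).
#'
#' @inheritParams detect_exon_skipping
#' @param window Maximum breakpoint-to-breakpoint distance in bases (default
#'   20000).
#' @return A data.frame of class `splice_events` (kind `"fusion"`) with donor
#'   and acceptor genes, breakpoint codes and labels, coordinates, junction
#'   key and ambiguity flag.
#' @export
detect_fusions <- function(jt, genes, window = 20000) {
  stopifnot(inherits(jt, "junction_table"))
  genes <- as_gene_models(genes)
  spans <- gene_spans(genes)
  j <- jt$junctions
  rows <- list()
  for (i in seq_len(nrow(j))) {
    if (j$right_start[i] - j$left_end[i] - 1L > window) next
    for (s in c("+", "-")) {
      if (j$strand[i] %in% c("+", "-") && j$strand[i] != s) next
      dpos <- if (s == "+") j$left_end[i] else j$right_start[i]
      apos <- if (s == "+") j$right_start[i] else j$left_end[i]
      ga <- spans$gene_id[spans$chrom == j$chrom[i] & spans$strand == s &
                            spans$start <= dpos & spans$end >= dpos]
      gb <- spans$gene_id[spans$chrom == j$chrom[i] & spans$strand == s &
                            spans$start <= apos & spans$end >= apos]
      for (A in ga) for (B in gb) {
        if (A == B) next
        bpd <- annotate_breakpoint(dpos, genes[genes$gene_id == A, ])
        bpa <- annotate_breakpoint(apos, genes[genes$gene_id == B, ])
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "fusion",
          gene_id = A, gene_id2 = B,
          chrom = j$chrom[i], strand = s,
          donor_exon = bpd$exon_a, acceptor_exon = bpa$exon_a,
          n_exons_donor = bpd$n_exons, n_exons_acceptor = bpa$n_exons,
          skipped_exons = NA_character_,
          donor_code = bpd$code, acceptor_code = bpa$code,
          donor_label = bpd$label, acceptor_label = bpa$label,
          left_end = j$left_end[i], right_start = j$right_start[i],
          junction_key = rownames(j)[i],
          ambiguous = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  ev <- rbind_events(rows)
  flag_ambiguous(ev)
}

gene_spans <- function(genes) {
  sp <- split(genes, genes$gene_id)
  data.frame(gene_id = names(sp),
             chrom = vapply(sp, function(g) g$chrom[1], ""),
             strand = vapply(sp, function(g) g$strand[1], ""),
             start = vapply(sp, function(g) min(g$start), 0),
             end = vapply(sp, function(g) max(g$end), 0),
             stringsAsFactors = FALSE)
}

as_gene_models <- function(genes) {
  if (inherits(genes, "gene_models")) genes else gene_models(genes)
}

rbind_events <- function(rows) {
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), gene_id = character(),
               gene_id2 = character(), chrom = character(),
               strand = character(), donor_exon = integer(),
               acceptor_exon = integer(), n_exons_donor = integer(),
               n_exons_acceptor = integer(), skipped_exons = character(),
               donor_code = character(), acceptor_code = character(),
               donor_label = character(), acceptor_label = character(),
               left_end = integer(), right_start = integer(),
               junction_key = character(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  class(ev) <- c("splice_events", "data.frame")
  ev
}

flag_ambiguous <- function(ev) {
  if (nrow(ev) > 0)
    ev$ambiguous <- ave(seq_len(nrow(ev)), ev$junction_key,
                        FUN = length) > 1
  ev
}

#' Annotate a breakpoint position relative to a gene's exon structure
#'
#' Codes, in transcription order: `B` when the position equals an exon's
#' transcription-order start (its 5' boundary), `E` when it equals an exon's
#' transcription-order end, `M` strictly inside an exon body, `I` inside the
#' intron between transcription-adjacent exons k and k+1 (both indices
#' reported), and `flanking` outside the gene span. A position matching both
#' boundaries of a one-base exon codes as `B`.
#'
#' @param position 1-based genomic position.
#' @param gene The exon rows of one gene from a [gene_models()] table.
#' @return List of class `breakpoint`: `code`, `exon_a`, `exon_b` (second
#'   intron-flanking exon or NA), `n_exons`, `label` (e.g. `"E Exon5 (12)"`,
#'   `"I Exon16-Exon17 (19)"`).
#' @export
annotate_breakpoint <- function(position, gene) {
  stopifnot(nrow(gene) > 0, length(unique(gene$gene_id)) == 1)
  g <- gene[order(gene$exon_number), , drop = FALSE]
  plus <- g$strand[1] == "+"
  n <- g$n_exons[1]
  tx_start <- if (plus) g$start else g$end   # 5' boundary per exon
  tx_end <- if (plus) g$end else g$start     # 3' boundary per exon
  code <- NULL
  if (position < min(g$start) || position > max(g$end)) {
    code <- list(code = "flanking", exon_a = NA_integer_,
                 exon_b = NA_integer_, n_exons = n,
                 label = sprintf("flanking (%d)", n))
  } else if (any(hit <- tx_start == position)) {
    e <- g$exon_number[which(hit)[1]]
    code <- list(code = "B", exon_a = e, exon_b = NA_integer_, n_exons = n,
                 label = sprintf("B Exon%d (%d)", e, n))
  } else if (any(hit <- tx_end == position)) {
    e <- g$exon_number[which(hit)[1]]
    code <- list(code = "E", exon_a = e, exon_b = NA_integer_, n_exons = n,
                 label = sprintf("E Exon%d (%d)", e, n))
  } else if (any(hit <- g$start < position & position < g$end)) {
    e <- g$exon_number[which(hit)[1]]
    code <- list(code = "M", exon_a = e, exon_b = NA_integer_, n_exons = n,
                 label = sprintf("M Exon%d (%d)", e, n))
  } else {
    # inside an intron: find the transcription-adjacent exon pair around it
    for (k in seq_len(n - 1)) {
      lo <- min(tx_end[k], tx_start[k + 1])
      hi <- max(tx_end[k], tx_start[k + 1])
      if (lo < position && position < hi) {
        code <- list(code = "I", exon_a = k, exon_b = k + 1L, n_exons = n,
                     label = sprintf("I Exon%d-Exon%d (%d)", k, k + 1L, n))
        break
      }
    }
    if (is.null(code))
      stop("breakpoint position ", position,
           " could not be placed in gene ", g$gene_id[1])
  }
  class(code) <- "breakpoint"
  code
}

#' Filter events on mean support and group difference
#'
#' Keeps events whose supporting junction has mean normalized count across
#' all samples of at least `min_mean_support`. When `min_group_diff` is set,
#' additionally requires the absolute difference of the two group means to
#' reach it; left `NULL` (the default) the difference filter is skipped.
#'
#' @param events A `splice_events` table.
#' @param jt The `junction_table` the events were called from (normalized on
#'   the fly if needed).
#' @param min_mean_support Minimum all-sample mean normalized support
#'   (default 3).
#' @param min_group_diff Optional minimum |mean(group1) - mean(group2)|.
#' @return The filtered `splice_events` table.
#' @export
filter_events <- function(events, jt, min_mean_support = 3,
                          min_group_diff = NULL) {
  stopifnot(inherits(events, "splice_events"))
  if (nrow(events) == 0) return(events)
  if (is.null(jt$norm)) jt <- normalize_counts(jt)
  cn <- jt$norm[events$junction_key, , drop = FALSE]
  keep <- rowMeans(cn) >= min_mean_support
  if (!is.null(min_group_diff)) {
    gl <- unique(jt$samples$group)
    if (length(gl) != 2)
      stop("the group-difference filter needs exactly two groups")
    m1 <- rowMeans(cn[, jt$samples$group == gl[1], drop = FALSE])
    m2 <- rowMeans(cn[, jt$samples$group == gl[2], drop = FALSE])
    keep <- keep & abs(m1 - m2) >= min_group_diff
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("splice_events", "data.frame")
  out
}

#' @export
print.splice_events <- function(x, ...) {
  cat("splice_events:", sum(x$kind == "exon_skipping"), "exon skipping,",
      sum(x$kind == "fusion"), "fusion\n")
  NextMethod()
}
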