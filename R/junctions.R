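#' Extract exon-exon splice junctions from spliced alignments
#'
#' Walks the CIGAR string of every uniquely mapped record and emits one
#' junction per `N` (skipped-region) operation, subject to the overhang rule:
#' the aligned blocks flanking the gap must each carry at least `min_overhang`
#' read bases aligned to the reference (`M`/`=`/`X` operations). A read with k
#' gaps contributes to k junctions, each gap judged on its own flanking
#' blocks. Multi-mapped records (`NH > 1` or the secondary-alignment flag) are
#' skipped, as are supplementary segments of two-segment reads; records whose
#' CIGAR cannot be parsed are skipped with a warning and counted.
#'
#' Junction coordinates are 1-based and fully closed: `left_end` is the last
#' aligned base of the upstream block and `right_start` the first aligned base
#' of the downstream block, so the intron occupies
#' `[left_end + 1, right_start - 1]`. Gaps shorter than 3 bases (too short to
#' carry two splice-site dinucleotides) are dropped.
#'
#' @param alignments A named list of per-sample alignment tables (see
#'   [read_alignments()]), or a single table (treated as one sample).
#' @param samples Optional sample sheet: data.frame with `sample`, `group`
#'   and optionally `total_mapped`. When `total_mapped` is absent it is
#'   computed as the number of distinct uniquely mapped read names per sample.
#' @param min_overhang Minimum aligned bases required on each side of a
#'   junction (default 8).
#' @return A `junction_table`: a list with `junctions` (data.frame `chrom`,
#'   `left_end`, `right_start`, `strand`, `motif`; strand/motif are filled by
#'   [classify_motif()]), `counts` (junction-by-sample raw support matrix),
#'   `norm` (normalized counts, `NULL` until [normalize_counts()]), and
#'   `samples`. The number of records skipped for malformed CIGARs is kept in
#'   `attr(, "n_malformed")`.
#' @examples
#' aln <- data.frame(qname = "r1", flag = 0L, chrom = "chr1", pos = 100L,
#'                   mapq = 60L, cigar = "10M100N10M", strand = "+",
#'                   nh = 1L, xo = NA_integer_, supplementary = FALSE)
#' jt <- extract_junctions(list(s1 = aln))
#' jt$junctions  # left_end 109, right_start 210
#' @export
extract_junctions <- function(alignments, samples = NULL, min_overhang = 8) {
  if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
  if (is.null(names(alignments)) || anyNA(names(alignments)))
    stop("alignments must be a named list of per-sample tables")
  if (is.null(samples)) {
    samples <- data.frame(sample = names(alignments),
                          group = NA_character_, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (!all(samples$sample %in% names(alignments)))
    stop("sample sheet names a sample with no alignment table")
  if (is.null(samples$total_mapped)) {
    samples$total_mapped <- vapply(samples$sample, function(s) {
      a <- alignments[[s]]
      keep <- unique_primary(a)
      length(unique(a$qname[keep]))
    }, 0L)
  }

  n_malformed <- 0L
  per_sample <- vector("list", nrow(samples))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(samples))) {
    a <- alignments[[samples$sample[i]]]
    a <- a[unique_primary(a) & grepl("N", a$cigar, fixed = TRUE), ,
           drop = FALSE]
    if (nrow(a) == 0) {
      per_sample[[i]] <- data.frame(key = character(), chrom = character(),
                                    left_end = integer(),
                                    right_start = integer(), n = integer(),
                                    stringsAsFactors = FALSE)
      next
    }
    offs <- lapply(a$cigar, cigar_junction_offsets, cache = cache)
    bad <- vapply(offs, is.null, TRUE)
    n_malformed <- n_malformed + sum(bad)
    rows <- vapply(offs, function(o) if (is.null(o)) 0L else nrow(o), 0L)
    rec <- rep.int(seq_len(nrow(a)), rows)
    o <- do.call(rbind, offs[!bad & rows > 0])
    if (is.null(o) || nrow(o) == 0) {
      per_sample[[i]] <- data.frame(key = character(), chrom = character(),
                                    left_end = integer(),
                                    right_start = integer(), n = integer(),
                                    stringsAsFactors = FALSE)
      next
    }
    j <- data.frame(chrom = a$chrom[rec],
                    left_end = a$pos[rec] + o$off_left,
                    right_start = a$pos[rec] + o$off_right,
                    loh = o$loh, roh = o$roh, stringsAsFactors = FALSE)
    j <- j[j$loh >= min_overhang & j$roh >= min_overhang &
             j$right_start - j$left_end >= 4L, , drop = FALSE]
    if (nrow(j) == 0) {
      per_sample[[i]] <- data.frame(key = character(), chrom = character(),
                                    left_end = integer(),
                                    right_start = integer(), n = integer(),
                                    stringsAsFactors = FALSE)
      next
    }
    key <- paste(j$chrom, j$left_end, j$right_start, sep = ":")
    tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(tab$key, ":", fixed = TRUE))
    per_sample[[i]] <- data.frame(key = tab$key, chrom = parts[, 1],
                                  left_end = as.integer(parts[, 2]),
                                  right_start = as.integer(parts[, 3]),
                                  n = tab$Freq, stringsAsFactors = FALSE)
  }
  if (n_malformed > 0)
    warning("skipped ", n_malformed, " record(s) with malformed CIGAR")

  all_keys <- unique(do.call(rbind, lapply(per_sample, function(d)
    d[, c("key", "chrom", "left_end", "right_start")])))
  all_keys <- all_keys[order(all_keys$chrom, all_keys$left_end,
                             all_keys$right_start), , drop = FALSE]
  counts <- matrix(0L, nrow(all_keys), nrow(samples),
                   dimnames = list(all_keys$key, samples$sample))
  for (i in seq_len(nrow(samples))) {
    d <- per_sample[[i]]
    counts[match(d$key, all_keys$key), i] <- d$n
  }
  junctions <- data.frame(chrom = all_keys$chrom,
                          left_end = all_keys$left_end,
                          right_start = all_keys$right_start,
                          strand = rep("*", nrow(all_keys)),
                          motif = rep(NA_character_, nrow(all_keys)),
                          stringsAsFactors = FALSE)
  rownames(junctions) <- all_keys$key
  out <- list(junctions = junctions, counts = counts, norm = NULL,
              samples = samples)
  attr(out, "n_malformed") <- n_malformed
  class(out) <- "junction_table"
  out
}

unique_primary <- function(a) {
  nh <- if (is.null(a$nh)) rep(NA_integer_, nrow(a)) else a$nh
  sup <- if (is.null(a$supplementary)) bitwAnd(a$flag, 2048L) > 0
         else a$supplementary
  (is.na(nh) | nh == 1L) & bitwAnd(a$flag, 256L) == 0L & !sup
}

# Offsets of each N gap relative to the record's leftmost aligned base, with
# the aligned (M/=/X) read-base run on each side. NULL for malformed CIGARs.
cigar_junction_offsets <- function(cigar, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[cigar]])) return(cache[[cigar]])
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  res <- NULL
  if (length(toks) > 0 && identical(paste(toks, collapse = ""), cigar)) {
    lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    refc <- ops %in% c("M", "D", "N", "=", "X")
    aligned <- ops %in% c("M", "=", "X")
    ref_before <- cumsum(c(0L, (lens * refc)[-length(lens)]))
    nidx <- which(ops == "N")
    if (length(nidx) > 0) {
      seg <- cumsum(ops == "N")  # aligned-run index, 0-based before first N
      runs <- vapply(0:max(seg), function(k)
        sum(lens[aligned & seg == k]), 0L)
      res <- data.frame(off_left = ref_before[nidx] - 1L,
                        off_right = ref_before[nidx] + lens[nidx],
                        loh = runs[seg[nidx]],        # run before this N
                        roh = runs[seg[nidx] + 1L])   # run after this N
    } else {
      res <- data.frame(off_left = integer(), off_right = integer(),
                        loh = integer(), roh = integer())
    }
  }
  if (!is.null(cache)) cache[[cigar]] <- if (is.null(res)) NULL else res
  res
}

#' Classify splice-site dinucleotide motifs against a genome
#'
#' Reads the intron boundary dinucleotides for each junction and assigns one
#' of `GT/AG`, `GC/AG`, `AT/AC` or `other`. On the plus strand the donor
#' dinucleotide is the first two intron bases
#' (`genome[left_end+1 .. left_end+2]`) and the acceptor the last two
#' (`genome[right_start-2 .. right_start-1]`); on the minus strand the same
#' two positions are read reverse-complemented and swapped so classification
#' happens in transcription orientation. For junctions of unknown strand
#' (`"*"`, the usual case for an unstranded library) both orientations are
#' tried and the one matching a consensus class (GT/AG, GC/AG or AT/AC) wins,
#' also resolving the strand; if both or neither orientation matches, the
#' motif is `other` and the strand stays unknown.
#'
#' @param x A `junction_table` (motif and strand columns are filled in and
#'   the table returned) or a data.frame with columns `chrom`, `left_end`,
#'   `right_start`, `strand` (a data.frame with `motif`/`strand` is returned).
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return Same class as `x`, with `motif` and (where inferred) `strand`
#'   filled.
#' @export
classify_motif <- function(x, genome) {
  genome <- load_genome(genome)
  j <- if (inherits(x, "junction_table")) x$junctions else x
  missing_chr <- setdiff(unique(j$chrom), names(genome))
  if (length(missing_chr))
    stop("genome does not cover chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  oob <- j$left_end < 1L | j$right_start - 1L > lens[j$chrom] |
    j$right_start - j$left_end < 4L
  if (any(oob)) {
    i <- which(oob)[1]
    stop(sprintf("junction outside genome bounds: %s:%d-%d",
                 j$chrom[i], j$left_end[i], j$right_start[i]))
  }
  left_di <- extract_dinuc(genome, j$chrom, j$left_end + 1L)
  right_di <- extract_dinuc(genome, j$chrom, j$right_start - 2L)
  plus <- classify_dinucleotides(left_di, right_di)
  minus <- classify_dinucleotides(revcomp_chr(right_di), revcomp_chr(left_di))
  consensus <- c("GT/AG", "GC/AG", "AT/AC")
  motif <- character(nrow(j))
  strand <- j$strand
  for (i in seq_len(nrow(j))) {
    if (strand[i] == "+") motif[i] <- plus[i]
    else if (strand[i] == "-") motif[i] <- minus[i]
    else {
      pc <- plus[i] %in% consensus
      mc <- minus[i] %in% consensus
      if (pc && !mc) { motif[i] <- plus[i]; strand[i] <- "+" }
      else if (mc && !pc) { motif[i] <- minus[i]; strand[i] <- "-" }
      else motif[i] <- "other"
    }
  }
  if (inherits(x, "junction_table")) {
    x$junctions$motif <- motif
    x$junctions$strand <- strand
    x
  } else {
    x$motif <- motif
    x$strand <- strand
    x
  }
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  genome
}

extract_dinuc <- function(genome, chrom, start) {
  vapply(seq_along(chrom), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], start[i],
                                    start[i] + 1L)),
    character(1))
}

# Map transcription-orientation donor/acceptor dinucleotides to a motif class.
classify_dinucleotides <- function(donor, acceptor) {
  pair <- paste(donor, acceptor, sep = "/")
  ifelse(pair %in% c("GT/AG", "GC/AG", "AT/AC"), pair, "other")
}

#' Normalize junction counts by library size
#'
#' Scales each sample's raw junction counts by
#' `mean(total_mapped over all samples) / total_mapped[sample]`, so the
#' normalized library sizes are equal and their sum is conserved. Raw counts
#' are retained alongside.
#'
#' @param jt A `junction_table` whose sample sheet carries `total_mapped`.
#' @return The `junction_table` with its `norm` matrix filled.
#' @examples
#' # totals 50 and 100, raw count 10 in each -> normalized 15 and 7.5
#' @export
normalize_counts <- function(jt) {
  stopifnot(inherits(jt, "junction_table"))
  totals <- jt$samples$total_mapped
  if (is.null(totals) || anyNA(totals))
    stop("per-sample total mapped reads are required for normalization")
  if (any(totals == 0)) stop("sample with zero total mapped reads: ",
                             jt$samples$sample[which(totals == 0)[1]])
  fac <- mean(totals) / totals
  jt$norm <- sweep(jt$counts, 2L, fac, `*`)
  jt
}

#' Summarize junctions per sample and per group
#'
#' Produces the per-sample and per-group summary of a junction table: the
#' junction reads as a percentage of each sample's mapped reads, and the
#' motif-class composition of the junction sites passing the mean-support
#' filter (mean normalized count across all samples at least
#' `min_mean_support`). A site contributes to a sample's motif percentages
#' when it is detected (raw count > 0) in that sample. Group rows report
#' mean and standard deviation over replicates, with a two-sided
#' pooled-variance t-test between the two groups where both have at least two
#' replicates.
#'
#' @param jt A `junction_table` with motifs assigned (see [classify_motif()]);
#'   normalized counts are computed on the fly if missing.
#' @param min_mean_support Mean-normalized-count filter for a junction site to
#'   enter the motif composition (default 3).
#' @return A list of class `junction_summary` with `per_sample` and
#'   `per_group` data.frames, plus `n_junctions` (all sites) and
#'   `n_supported` (sites passing the filter).
#' @export
summarize_junctions <- function(jt, min_mean_support = 3) {
  stopifnot(inherits(jt, "junction_table"))
  if (is.null(jt$norm)) {
    if (nrow(jt$counts) > 0) jt <- normalize_counts(jt)
    else jt$norm <- jt$counts
  }
  if (all(is.na(jt$junctions$motif)) && nrow(jt$junctions) > 0)
    stop("assign motifs with classify_motif() before summarizing")
  totals <- jt$samples$total_mapped
  supported <- if (nrow(jt$counts) > 0)
    rowMeans(jt$norm) >= min_mean_support else logical(0)
  classes <- c("GT/AG", "GC/AG", "AT/AC", "other")
  per_sample <- data.frame(sample = jt$samples$sample,
                           group = jt$samples$group,
                           total_mapped = totals,
                           junction_reads_pct =
                             ifelse(totals > 0,
                                    100 * colSums(jt$counts) / totals,
                                    NA_real_),
                           stringsAsFactors = FALSE)
  for (cl in classes) per_sample[[paste0("pct_", cl)]] <- NA_real_
  for (i in seq_len(nrow(per_sample))) {
    det <- supported & jt$counts[, i] > 0
    nm <- sum(det)
    for (cl in classes)
      per_sample[[paste0("pct_", cl)]][i] <-
        if (nm > 0) 100 * sum(jt$junctions$motif[det] == cl) / nm else NA_real_
  }
  rownames(per_sample) <- NULL

  metrics <- c("total_mapped", "junction_reads_pct",
               paste0("pct_", classes))
  groups <- unique(per_sample$group[!is.na(per_sample$group)])
  per_group <- NULL
  if (length(groups) >= 1) {
    per_group <- data.frame(metric = metrics, stringsAsFactors = FALSE)
    for (g in groups) {
      v <- per_sample[per_sample$group %in% g, metrics, drop = FALSE]
      per_group[[paste0("mean_", g)]] <- vapply(v, mean, 0, na.rm = TRUE)
      per_group[[paste0("sd_", g)]] <- vapply(v, stats::sd, 0, na.rm = TRUE)
    }
    if (length(groups) == 2) {
      g1 <- per_sample$group %in% groups[1]
      g2 <- per_sample$group %in% groups[2]
      per_group$p_value <- vapply(metrics, function(m) {
        x <- per_sample[[m]][g1]; y <- per_sample[[m]][g2]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) return(NA_real_)
        pooled_t_test(x, y)$p
      }, 0)
    }
  }
  out <- list(per_sample = per_sample, per_group = per_group,
              n_junctions = nrow(jt$junctions),
              n_supported = sum(supported),
              min_mean_support = min_mean_support)
  class(out) <- "junction_summary"
  out
}

#' @export
print.junction_table <- function(x, ...) {
  cat("junction_table:", nrow(x$junctions), "junctions x",
      ncol(x$counts), "samples",
      if (!is.null(x$norm)) "(normalized)" else "(raw only)", "\n")
  if (nrow(x$junctions) > 0) {
    print(utils::head(cbind(x$junctions,
                            as.data.frame(x$counts)), 6))
    if (nrow(x$junctions) > 6) cat("...\n")
  }
  invisible(x)
}

#' @export
print.junction_summary <- function(x, ...) {
  cat("Junction summary:", x$n_junctions, "sites,", x$n_supported,
      "with mean normalized support >=", x$min_mean_support, "\n")
  if (!is.null(x$per_group)) {
    df <- x$per_group
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 4)
    print(df, row.names = FALSE)
  } else {
    print(x$per_sample, row.names = FALSE)
  }
  invisible(x)
}
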