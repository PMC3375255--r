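#' Read spliced alignments from a SAM or BAM file
#'
#' Loads one sample's alignments into the package's canonical alignment table.
#' SAM text is converted through [Rsamtools::asBam()] and records are read
#' with [GenomicAlignments::readGAlignments()], keeping the query name, flag,
#' CIGAR, mapping strand and the `NH` (number of hits) and `XO` (order of a
#' two-segment read's half within the read) tags.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file with a header.
#' @return A data.frame with columns `qname`, `flag`, `chrom`, `pos` (1-based
#'   leftmost aligned base), `mapq`, `cigar`, `strand`, `nh`, `xo`,
#'   `supplementary`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"),
                                   tag = c("NH", "XO"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(gal)
  nh <- md$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(gal))
  xo <- md$XO
  if (is.null(xo)) xo <- rep(NA_integer_, length(gal))
  data.frame(
    qname = as.character(md$qname),
    flag = as.integer(md$flag),
    chrom = as.character(GenomicAlignments::seqnames(gal)),
    pos = GenomicAlignments::start(gal),
    mapq = as.integer(md$mapq),
    cigar = GenomicAlignments::cigar(gal),
    strand = as.character(GenomicAlignments::strand(gal)),
    nh = as.integer(nh),
    xo = as.integer(xo),
    supplementary = bitwAnd(as.integer(md$flag), 2048L) > 0L,
    stringsAsFactors = FALSE)
}

#' Write an alignment table as SAM text
#'
#' Emits a minimal valid SAM file (header plus one line per record) from the
#' canonical alignment table used throughout the package. Sequences and
#' qualities are written as `*`; `NH` and, for two-segment reads, `XO` tags
#' are carried.
#'
#' @param aln Alignment table as returned by [read_alignments()] (columns
#'   `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`, `nh`, `xo`).
#' @param path Output path.
#' @param seqlengths Named integer vector of reference sequence lengths for
#'   the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  tags <- sprintf("NH:i:%d", aln$nh)
  has_xo <- !is.na(aln$xo)
  tags[has_xo] <- paste0(tags[has_xo], sprintf("\tXO:i:%d", aln$xo[has_xo]))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\t%s",
                  aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq,
                  aln$cigar, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}
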