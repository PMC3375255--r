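# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: junction coordinates come from a per-base
# reconstruction of the alignment, and t-tail probabilities from numeric
# integration of the t density.

# Per-base reconstruction: lay every aligned read base onto its reference
# position, then read junctions off the block structure.
oracle_junctions <- function(pos, cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  ops <- sub("^[0-9]+", "", toks)
  refpos <- pos
  ref_of_base <- integer(0)
  block_of_base <- integer(0)
  bid <- 1L
  for (t in seq_along(ops)) {
    if (ops[t] %in% c("M", "=", "X")) {
      ref_of_base <- c(ref_of_base, seq.int(refpos, length.out = lens[t]))
      block_of_base <- c(block_of_base, rep(bid, lens[t]))
      refpos <- refpos + lens[t]
    } else if (ops[t] == "D") {
      refpos <- refpos + lens[t]
    } else if (ops[t] == "N") {
      refpos <- refpos + lens[t]
      bid <- bid + 1L
    }
  }
  if (bid == 1L)
    return(data.frame(left_end = integer(), right_start = integer(),
                      loh = integer(), roh = integer()))
  do.call(rbind, lapply(seq_len(bid - 1L), function(k) {
    data.frame(left_end = max(ref_of_base[block_of_base == k]),
               right_start = min(ref_of_base[block_of_base == k + 1L]),
               loh = sum(block_of_base == k),
               roh = sum(block_of_base == k + 1L))
  }))
}

# Two-sided t tail probability by numeric integration of the density.
oracle_t_p <- function(tstat, df) {
  if (!is.finite(tstat)) return(0)
  if (tstat == 0) return(1)
  2 * stats::integrate(function(x) stats::dt(x, df), abs(tstat), Inf,
                       rel.tol = 1e-10)$value
}

# Plain-character reverse complement (independent of the package helper).
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
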