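# shared internal helpers

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Reverse complement of short plain-character DNA strings.
revcomp_chr <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Convert 1-based closed intervals to BED (0-based half-open) and back
#'
#' The package stores genomic coordinates 1-based and fully closed, the
#' convention of GTF and of printed junction positions; BED tracks are 0-based
#' half-open. These two helpers are the single conversion point used by every
#' writer.
#'
#' @param start,end 1-based closed interval bounds (`to_bed0`) or 0-based
#'   half-open bounds (`from_bed0`).
#' @return A data.frame with `start` and `end` in the other convention.
#' @examples
#' to_bed0(100, 200)    # -> start 99,  end 200
#' from_bed0(99, 200)   # -> start 100, end 200
#' @export
to_bed0 <- function(start, end) {
  stopifnot(all(end >= start))
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_bed0
#' @export
from_bed0 <- function(start, end) {
  stopifnot(all(end > start))
  data.frame(start = start + 1L, end = end)
}

# sample() without its length-1 surprise
sample_int <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}
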