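#' Group summary statistics
#'
#' @param x Numeric vector of (normalized) counts for one group.
#' @return A list of class `group_summary` with `n`, `mean`, `sd` (sample
#'   standard deviation, n-1 denominator).
#' @export
group_summary <- function(x) {
  stopifnot(is.numeric(x))
  out <- list(n = length(x), mean = mean(x),
              sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  class(out) <- "group_summary"
  out
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (!is.null(names(x)) && all(c("n", "mean", "sd") %in% names(x))) {
    out <- list(n = as.numeric(x[["n"]]), mean = as.numeric(x[["mean"]]),
                sd = as.numeric(x[["sd"]]))
    class(out) <- "group_summary"
    return(out)
  }
  if (is.numeric(x)) return(group_summary(unname(x)))
  stop("cannot interpret input as a group summary or numeric vector")
}

#' Two-sample t-test on group summaries or raw counts
#'
#' The differential-usage test of the pipeline: a two-sided pooled-variance
#' Student t-test with `df = n1 + n2 - 2`, computed either from raw
#' replicate values or directly from `(n, mean, sd)` summaries -- the two
#' routes agree exactly because the statistic depends on the data only
#' through those summaries. Recomputing from rounded published group
#' summaries therefore reproduces published p-values. Welch's unequal-variance
#' test is available behind `welch = TRUE`.
#'
#' Degenerate inputs: when both group variances are zero and the means are
#' equal the statistic is 0 and p = 1; when both variances are zero but the
#' means differ, the pooled SE is 0, so the result is flagged `degenerate`
#' with `t = +/-Inf` and p reported at the smallest positive double.
#'
#' @param a,b Numeric vectors of replicate values, or group summaries (a
#'   `group_summary`, or any list/vector with `n`, `mean`, `sd`).
#' @param welch Use the Welch-Satterthwaite degrees of freedom instead of the
#'   pooled variance (default `FALSE`).
#' @return A list of class `t_test_result`: `t`, `df`, `p`, `degenerate`,
#'   `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`, `method`.
#' @examples
#' # Two groups summarized as mean +/- sd with n = 4 each:
#' pooled_t_test(c(n = 4, mean = 10.25, sd = 4.50),
#'               c(n = 4, mean = 0.50, sd = 0.58))$p   # ~0.0051
#' @export
pooled_t_test <- function(a, b, welch = FALSE) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2)
    stop("each group needs at least 2 replicates")
  m1 <- a$mean; m2 <- b$mean; s1 <- a$sd; s2 <- b$sd
  n1 <- a$n; n2 <- b$n
  degenerate <- FALSE
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) {
      if (m1 == m2) { tstat <- 0; df <- n1 + n2 - 2; p <- 1 }
      else {
        tstat <- sign(m1 - m2) * Inf; df <- n1 + n2 - 2
        p <- .Machine$double.xmin; degenerate <- TRUE
      }
    } else {
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    if (sp2 == 0) {
      if (m1 == m2) { tstat <- 0; p <- 1 }
      else {
        tstat <- sign(m1 - m2) * Inf
        p <- .Machine$double.xmin; degenerate <- TRUE
      }
    } else {
      tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  out <- list(t = tstat, df = df, p = p, degenerate = degenerate,
              mean1 = m1, sd1 = s1, n1 = n1,
              mean2 = m2, sd2 = s2, n2 = n2,
              method = if (welch) "welch" else "pooled")
  class(out) <- "t_test_result"
  out
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4f, df = %.2f, p = %.4g%s\n",
              x$method, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate: zero pooled variance)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values, order-preserving, via
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Percent-spliced-in (Psi) point estimate with read-count filters
#'
#' A length-normalized density-ratio estimate of the inclusion fraction:
#' `psi = (inc / inc_pos) / (inc / inc_pos + exc / exc_pos)`, where the
#' position counts normalize for the number of read positions (junctions)
#' informative for each isoform. An event passes the read filter only when it
#' has at least one inclusion read, at least one exclusion read, and more
#' than 10 reads in total.
#'
#' @param inclusion_reads,exclusion_reads Read counts supporting the
#'   inclusion and exclusion isoforms.
#' @param inclusion_positions,exclusion_positions Number of informative read
#'   positions for each isoform (must be > 0).
#' @return List of class `psi_estimate`: `psi` (NA when both densities are
#'   zero), `inclusion`, `exclusion`, `passes_filter`.
#' @examples
#' estimate_psi(8, 2, 1, 1)$psi    # 0.8
#' @export
estimate_psi <- function(inclusion_reads, exclusion_reads,
                         inclusion_positions = 1, exclusion_positions = 1) {
  if (inclusion_positions <= 0 || exclusion_positions <= 0)
    stop("position counts must be > 0")
  if (inclusion_reads < 0 || exclusion_reads < 0)
    stop("read counts must be >= 0")
  di <- inclusion_reads / inclusion_positions
  de <- exclusion_reads / exclusion_positions
  psi <- if (di + de == 0) NA_real_ else di / (di + de)
  out <- list(psi = psi,
              inclusion = inclusion_reads, exclusion = exclusion_reads,
              passes_filter = inclusion_reads >= 1 && exclusion_reads >= 1 &&
                (inclusion_reads + exclusion_reads) > 10)
  class(out) <- "psi_estimate"
  out
}

#' RPKM and between-group fold change
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `rpkm = count * 1e9 / (exon_model_length * total)`, with the fold change
#' expressed as the ratio of group mean RPKMs (first group over second).
#'
#' @param counts Named or plain numeric vector of per-sample read counts for
#'   one gene.
#' @param exon_model_length Total exonic length of the gene model in bases.
#' @param totals Per-sample total mapped reads (same order as `counts`).
#' @param groups Optional group labels per sample; with exactly two groups the
#'   fold change mean(RPKM first group)/mean(RPKM second group) is computed.
#'   A zero denominator yields `fold = NA` with `induced_from_zero = TRUE`.
#' @return List of class `expression_summary`: `rpkm`, `fold`,
#'   `induced_from_zero`, `groups`.
#' @examples
#' rpkm_fold(1000, 1000, 1e7)$rpkm  # 100
#' @export
rpkm_fold <- function(counts, exon_model_length, totals, groups = NULL) {
  if (exon_model_length <= 0) stop("exon_model_length must be > 0")
  if (any(totals <= 0)) stop("totals must be > 0")
  rpkm <- counts * 1e9 / (exon_model_length * totals)
  fold <- NA_real_
  induced <- FALSE
  if (!is.null(groups)) {
    gl <- unique(groups)
    if (length(gl) != 2) stop("fold change needs exactly two groups")
    num <- mean(rpkm[groups == gl[1]])
    den <- mean(rpkm[groups == gl[2]])
    if (den > 0) fold <- num / den
    else induced <- num > 0
  }
  out <- list(rpkm = rpkm, fold = fold, induced_from_zero = induced,
              groups = groups)
  class(out) <- "expression_summary"
  out
}

#' @export
print.expression_summary <- function(x, ...) {
  cat("RPKM:", paste(signif(x$rpkm, 4), collapse = " "), "\n")
  if (!is.na(x$fold)) cat("fold change:", signif(x$fold, 4), "\n")
  else if (x$induced_from_zero) cat("fold change: induced from zero\n")
  invisible(x)
}
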