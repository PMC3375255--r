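#' Test all called events for differential junction usage
#'
#' Annotates every event with per-group summaries (n, mean, sd of normalized
#' junction counts), the two-sided pooled-variance t-test (or Welch's test),
#' Benjamini-Hochberg adjusted q-values across all tested events, and -- for
#' exon-skipping events when gene models are supplied -- a percent-spliced-in
#' estimate per group and its between-group difference. The inclusion isoform
#' is measured by the transcription-adjacent junctions flanking the skipped
#' block (donor exon to its successor, and the predecessor of the acceptor
#' exon to the acceptor exon); the exclusion isoform by the skip junction
#' itself. Events with zero raw counts in every sample are dropped with a
#' message. The result is sorted by p-value.
#'
#' @param events A `splice_events` table ([detect_exon_skipping()] /
#'   [detect_fusions()], usually after [filter_events()]).
#' @param jt The `junction_table` the events were called from; must carry a
#'   two-group sample sheet. Normalized on the fly if needed.
#' @param genes Optional [gene_models()] table enabling Psi estimation for
#'   skip events.
#' @param welch Use Welch's test instead of the pooled-variance test.
#' @param delta_psi_min Optional threshold: skip events with `|delta Psi|`
#'   below it (or with undefined Psi) are removed. `NULL` (default) applies
#'   no Psi filter. The conventional screening value is 0.20.
#' @return The `splice_events` table with columns `n1`, `mean1`, `sd1`, `n2`,
#'   `mean2`, `sd2`, `t`, `df`, `p`, `q`, `degenerate`, `psi1`, `psi2`,
#'   `delta_psi`, `psi_filter`; `attr(, "groups")` names the two groups in
#'   column order (group 1 minus group 2).
#' @export
test_all_events <- function(events, jt, genes = NULL, welch = FALSE,
                            delta_psi_min = NULL) {
  stopifnot(inherits(events, "splice_events"))
  if (is.null(jt$norm)) jt <- normalize_counts(jt)
  gl <- unique(jt$samples$group)
  if (length(gl) != 2) stop("event testing needs exactly two groups")
  g1 <- jt$samples$group == gl[1]
  g2 <- jt$samples$group == gl[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("each group needs at least 2 replicates")
  ev <- events
  if (nrow(ev) > 0) {
    raw <- jt$counts[ev$junction_key, , drop = FALSE]
    allzero <- rowSums(raw) == 0
    if (any(allzero)) {
      message("dropping ", sum(allzero),
              " event(s) with zero counts in every sample")
      ev <- ev[!allzero, , drop = FALSE]
    }
  }
  n <- nrow(ev)
  num <- function() rep(NA_real_, n)
  ev$n1 <- rep(sum(g1), n); ev$mean1 <- num(); ev$sd1 <- num()
  ev$n2 <- rep(sum(g2), n); ev$mean2 <- num(); ev$sd2 <- num()
  ev$t <- num(); ev$df <- num(); ev$p <- num(); ev$q <- num()
  ev$degenerate <- rep(FALSE, n)
  ev$psi1 <- num(); ev$psi2 <- num(); ev$delta_psi <- num()
  ev$psi_filter <- rep(NA, n)
  if (n > 0) {
    cn <- jt$norm[ev$junction_key, , drop = FALSE]
    raw <- jt$counts[ev$junction_key, , drop = FALSE]
    for (i in seq_len(n)) {
      x <- cn[i, g1]; y <- cn[i, g2]
      tt <- pooled_t_test(x, y, welch = welch)
      ev$mean1[i] <- tt$mean1; ev$sd1[i] <- tt$sd1
      ev$mean2[i] <- tt$mean2; ev$sd2[i] <- tt$sd2
      ev$t[i] <- tt$t; ev$df[i] <- tt$df; ev$p[i] <- tt$p
      ev$degenerate[i] <- tt$degenerate
      if (ev$kind[i] == "exon_skipping" && !is.null(genes)) {
        psi <- skip_event_psi(ev[i, ], jt, genes, g1, g2)
        ev$psi1[i] <- psi$psi1; ev$psi2[i] <- psi$psi2
        ev$delta_psi[i] <- psi$delta
        ev$psi_filter[i] <- psi$passes
      }
    }
    ev$q <- bh_fdr(ev$p)
    if (!is.null(delta_psi_min)) {
      drop <- ev$kind == "exon_skipping" &
        (is.na(ev$delta_psi) | abs(ev$delta_psi) < delta_psi_min)
      ev <- ev[!drop, , drop = FALSE]
    }
    ev <- ev[order(ev$p), , drop = FALSE]
    rownames(ev) <- NULL
  }
  class(ev) <- c("splice_events", "data.frame")
  attr(ev, "groups") <- gl
  ev
}

# Psi for one skip event: inclusion = the flanking transcription-adjacent
# junctions present in the table, exclusion = the skip junction.
skip_event_psi <- function(event, jt, genes, g1, g2) {
  genes <- as_gene_models(genes)
  i <- event$donor_exon; j <- event$acceptor_exon
  keys <- unique(stats::na.omit(c(
    adjacent_junction_key(genes, event$gene_id, i),
    adjacent_junction_key(genes, event$gene_id, j - 1L))))
  keys <- keys[keys %in% rownames(jt$counts)]
  inc_pos <- length(keys)
  if (inc_pos == 0)
    return(list(psi1 = NA_real_, psi2 = NA_real_, delta = NA_real_,
                passes = FALSE))
  inc_norm <- colSums(jt$norm[keys, , drop = FALSE])
  exc_norm <- jt$norm[event$junction_key, ]
  p1 <- estimate_psi(mean(inc_norm[g1]), mean(exc_norm[g1]), inc_pos, 1)
  p2 <- estimate_psi(mean(inc_norm[g2]), mean(exc_norm[g2]), inc_pos, 1)
  total_inc <- sum(jt$counts[keys, , drop = FALSE])
  total_exc <- sum(jt$counts[event$junction_key, ])
  passes <- estimate_psi(total_inc, total_exc, inc_pos, 1)$passes_filter
  delta <- if (is.na(p1$psi) || is.na(p2$psi)) NA_real_ else p1$psi - p2$psi
  list(psi1 = p1$psi, psi2 = p2$psi, delta = delta, passes = passes)
}

# key of the annotated junction joining transcription-order exons k and k+1
adjacent_junction_key <- function(genes, gene_id, k) {
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (k < 1 || k + 1 > g$n_exons[1]) return(NA_character_)
  a <- g[g$exon_number == k, ]
  b <- g[g$exon_number == k + 1, ]
  if (g$strand[1] == "+")
    paste(a$chrom, a$end, b$start, sep = ":")
  else
    paste(a$chrom, b$end, a$start, sep = ":")
}
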