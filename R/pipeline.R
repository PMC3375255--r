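#' Pipeline configuration
#'
#' Bundles and validates everything one end-to-end run needs: the sample
#' sheet, reference paths, output directory and the analysis parameters.
#'
#' @param sample_sheet data.frame with columns `sample`, `group`, `path`
#'   (per-sample SAM/BAM), or path to a TSV with those columns. Two groups
#'   with at least 2 samples each are required for testing.
#' @param genome Path to the genome FASTA (or a DNAStringSet).
#' @param gtf Path to the gene annotation GTF (or a GRanges / exon table).
#' @param outdir Output directory for [run_pipeline()].
#' @param min_overhang Junction overhang rule in bases (default 8).
#' @param window Fusion / consistency window in bases (default 20000).
#' @param min_mean_support Mean-support filter in reads (default 3).
#' @param min_group_diff Optional group-difference filter (default off).
#' @param delta_psi_min Optional |delta Psi| filter for skip events (default
#'   off; 0.20 is the conventional screening value).
#' @param welch Use Welch's test instead of the pooled-variance t-test.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, genome, gtf, outdir,
                            min_overhang = 8, window = 20000,
                            min_mean_support = 3, min_group_diff = NULL,
                            delta_psi_min = NULL, welch = FALSE) {
  if (is.character(sample_sheet) && length(sample_sheet) == 1)
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(sample_sheet),
            all(c("sample", "group", "path") %in% names(sample_sheet)))
  if (anyDuplicated(sample_sheet$sample))
    stop("duplicate sample ids in the sample sheet")
  tab <- table(sample_sheet$group)
  if (length(tab) == 2 && any(tab < 2))
    stop("each group needs at least 2 samples for testing")
  missing <- sample_sheet$path[!file.exists(sample_sheet$path)]
  if (length(missing))
    stop("alignment file(s) not found: ", paste(missing, collapse = ", "))
  if (is.character(genome) && !file.exists(genome))
    stop("genome FASTA not found: ", genome)
  if (is.character(gtf) && !file.exists(gtf))
    stop("annotation GTF not found: ", gtf)
  cfg <- list(sample_sheet = sample_sheet, genome = genome, gtf = gtf,
              outdir = outdir, min_overhang = min_overhang, window = window,
              min_mean_support = min_mean_support,
              min_group_diff = min_group_diff,
              delta_psi_min = delta_psi_min, welch = welch)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full junction analysis pipeline
#'
#' Executes junction extraction, motif classification, count normalization,
#' per-sample/group summaries, topology classification of two-segment reads,
#' exon-skipping and fusion calling, event filtering and differential
#' testing, then writes every table via [write_reports()]. The run is
#' deterministic: identical inputs give byte-identical output tables. Empty
#' alignment files yield empty tables and a warning rather than an error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `pipeline_result` with `jt` (junction
#'   table), `summary`, `topology` (per-sample label counts), `skipping` and
#'   `fusions` (tested event tables), `genes`, and `paths` (written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$outdir, 2) != 0)
    stop("output directory is not writable: ", config$outdir)

  sheet <- config$sample_sheet
  aln <- lapply(seq_len(nrow(sheet)), function(i)
    read_alignments(sheet$path[i]))
  names(aln) <- sheet$sample
  if (all(vapply(aln, nrow, 0L) == 0))
    warning("all alignment files are empty; writing empty tables")

  jt <- extract_junctions(aln, samples = sheet[, c("sample", "group")],
                          min_overhang = config$min_overhang)
  if (nrow(jt$junctions) > 0) jt <- classify_motif(jt, config$genome)
  if (all(jt$samples$total_mapped > 0)) jt <- normalize_counts(jt)
  summary <- summarize_junctions(jt,
                                 min_mean_support = config$min_mean_support)

  topo <- topology_counts(aln, window = config$window)

  genes <- as_gene_models(config$gtf)
  skipping <- detect_exon_skipping(jt, genes)
  fusions <- detect_fusions(jt, genes, window = config$window)
  if (!is.null(jt$norm)) {
    skipping <- filter_events(skipping, jt,
                              min_mean_support = config$min_mean_support,
                              min_group_diff = config$min_group_diff)
    fusions <- filter_events(fusions, jt,
                             min_mean_support = config$min_mean_support,
                             min_group_diff = config$min_group_diff)
    if (length(unique(jt$samples$group)) == 2) {
      skipping <- test_all_events(skipping, jt, genes = genes,
                                  welch = config$welch,
                                  delta_psi_min = config$delta_psi_min)
      fusions <- test_all_events(fusions, jt, genes = genes,
                                 welch = config$welch)
    }
  }
  res <- list(jt = jt, summary = summary, topology = topo,
              skipping = skipping, fusions = fusions, genes = genes)
  res$paths <- write_reports(res, config)
  class(res) <- "pipeline_result"
  invisible(res)
}

# per-sample counts of each topology label over the two-segment reads
topology_counts <- function(aln, window = 20000) {
  labels <- c("consistent", "scramble", "inversion", "translocation",
              "distant")
  out <- data.frame(sample = names(aln), stringsAsFactors = FALSE)
  for (l in labels) out[[l]] <- 0L
  for (i in seq_along(aln)) {
    pairs <- read_half_pairs(aln[[i]])
    if (nrow(pairs) == 0) next
    tab <- table(factor(classify_topology(pairs, window = window),
                        levels = labels))
    out[i, labels] <- as.integer(tab)
  }
  out
}

#' Write the pipeline's report bundle
#'
#' Writes TSV tables (junction table with raw and normalized counts, the
#' per-sample and per-group summaries, topology counts, tested skipping and
#' fusion event tables), BED12 tracks for the called events (coordinates
#' converted to the BED 0-based half-open convention through [to_bed0()]),
#' a JSON summary whose counts equal the table row counts, and a run log with
#' the resolved parameters and package version.
#'
#' @param res The pipeline result list (see [run_pipeline()]).
#' @param config The [pipeline_config()] of the run.
#' @return Named list of written file paths.
#' @export
write_reports <- function(res, config) {
  out <- config$outdir
  tsv <- function(x, f) {
    p <- file.path(out, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  jt <- res$jt
  jdf <- cbind(junction = rownames(jt$junctions), jt$junctions,
               as.data.frame(jt$counts, check.names = FALSE))
  if (!is.null(jt$norm)) {
    nm <- as.data.frame(jt$norm, check.names = FALSE)
    names(nm) <- paste0("norm_", names(nm))
    jdf <- cbind(jdf, nm)
  }
  paths <- list(
    junctions = tsv(jdf, "junctions.tsv"),
    summary_per_sample = tsv(res$summary$per_sample,
                             "summary_per_sample.tsv"),
    summary_per_group = if (!is.null(res$summary$per_group))
      tsv(res$summary$per_group, "summary_per_group.tsv") else NULL,
    topology = tsv(res$topology, "topology.tsv"),
    skipping = tsv(format_event_table(res$skipping),
                   "events_skipping.tsv"),
    fusions = tsv(format_event_table(res$fusions), "events_fusion.tsv"),
    skipping_bed = write_events_bed(res$skipping, res$genes,
                                    file.path(out, "events_skipping.bed")),
    fusion_bed = write_events_bed(res$fusions, res$genes,
                                  file.path(out, "events_fusion.bed")))

  js <- list(
    n_samples = nrow(jt$samples),
    n_junctions = nrow(jt$junctions),
    n_supported = res$summary$n_supported,
    n_skipping = nrow(res$skipping),
    n_fusion = nrow(res$fusions),
    n_malformed_records = attr(jt, "n_malformed"),
    parameters = config[c("min_overhang", "window", "min_mean_support",
                          "min_group_diff", "delta_psi_min", "welch")])
  paths$json <- file.path(out, "summary.json")
  jsonlite::write_json(js, paths$json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")

  log <- c(paste0("splicescope ",
                  as.character(utils::packageVersion("splicescope"))),
           paste0("R ", R.version$major, ".", R.version$minor),
           "parameters:",
           paste0("  min_overhang = ", config$min_overhang),
           paste0("  window = ", config$window),
           paste0("  min_mean_support = ", config$min_mean_support),
           paste0("  min_group_diff = ",
                  if (is.null(config$min_group_diff)) "off"
                  else config$min_group_diff),
           paste0("  delta_psi_min = ",
                  if (is.null(config$delta_psi_min)) "off"
                  else config$delta_psi_min),
           paste0("  test = ", if (config$welch) "welch" else "pooled"),
           "samples:",
           paste0("  ", config$sample_sheet$sample, " (",
                  config$sample_sheet$group, "): ",
                  config$sample_sheet$path))
  paths$log <- file.path(out, "run_log.txt")
  writeLines(log, paths$log)
  paths
}

# printable event table mirroring the published layouts; positions are shown
# as strand-prefixed 1-based coordinates ("-chr7:15803726" style)
format_event_table <- function(ev) {
  if (nrow(ev) == 0) {
    df <- as.data.frame(ev)
    return(df)
  }
  donor_pos <- ifelse(ev$strand == "-", ev$right_start, ev$left_end)
  acc_pos <- ifelse(ev$strand == "-", ev$left_end, ev$right_start)
  df <- data.frame(
    kind = ev$kind,
    donor_gene = ev$gene_id,
    acceptor_gene = ifelse(is.na(ev$gene_id2), ev$gene_id, ev$gene_id2),
    junction = ev$junction_key,
    donor = sprintf("%s%s:%d", ev$strand, ev$chrom, donor_pos),
    acceptor = sprintf("%s%s:%d", ev$strand, ev$chrom, acc_pos),
    donor_site = ev$donor_label,
    acceptor_site = ev$acceptor_label,
    exons_skipped = ifelse(is.na(ev$skipped_exons), "",
                           vapply(strsplit(ev$skipped_exons, ","),
                                  function(x) paste0("Exon#", x,
                                                     collapse = " & "),
                                  "")),
    ambiguous = ev$ambiguous,
    stringsAsFactors = FALSE)
  stat_cols <- intersect(c("mean1", "sd1", "mean2", "sd2", "t", "df", "p",
                           "q", "degenerate", "psi1", "psi2", "delta_psi",
                           "psi_filter"), names(ev))
  for (cl in stat_cols)
    df[[cl]] <- if (is.numeric(ev[[cl]])) round(ev[[cl]], 4) else ev[[cl]]
  df
}

# BED12 export: skip events carry the two flanking exons as blocks; fusions
# carry one-base blocks at the two breakpoints
write_events_bed <- function(ev, genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(ev))) {
    if (ev$kind[i] == "exon_skipping") {
      g <- genes[genes$gene_id == ev$gene_id[i], ]
      d <- g[g$exon_number == ev$donor_exon[i], ]
      a <- g[g$exon_number == ev$acceptor_exon[i], ]
      s1 <- min(d$start, a$start); e2 <- max(d$end, a$end)
      b <- to_bed0(s1, e2)
      blocks <- rbind(to_bed0(min(d$start, a$start),
                              min(d$end, a$end)),
                      to_bed0(max(d$start, a$start), max(d$end, a$end)))
      name <- sprintf("%s_skip_E%d-E%d", ev$gene_id[i], ev$donor_exon[i],
                      ev$acceptor_exon[i])
    } else {
      b <- to_bed0(ev$left_end[i], ev$right_start[i])
      blocks <- rbind(to_bed0(ev$left_end[i], ev$left_end[i]),
                      to_bed0(ev$right_start[i], ev$right_start[i]))
      name <- sprintf("%s-%s_fusion", ev$gene_id[i], ev$gene_id2[i])
    }
    lines <- c(lines, paste(
      ev$chrom[i], b$start, b$end, name, 0,
      if (ev$strand[i] %in% c("+", "-")) ev$strand[i] else ".",
      b$start, b$end, "0,0,0", nrow(blocks),
      paste0(paste(blocks$end - blocks$start, collapse = ","), ","),
      paste0(paste(blocks$start - b$start, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  path
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$jt$junctions), "junctions;",
      nrow(x$skipping), "skipping and", nrow(x$fusions),
      "fusion events\n")
  invisible(x)
}
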