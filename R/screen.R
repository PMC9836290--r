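#' Run the full replication-arrest survival screen
#'
#' Executes the fixed stage order: per-sample low-coverage filtering,
#' inter-sample quantile normalization over the union of retained
#' positions (absent positions contribute zeros to the normalization but
#' are not re-introduced into a sample's profile), gene-level
#' aggregation over the internal window, generation-matched pairing,
#' log2 fold changes and classification. Deterministic given its
#' inputs.
#'
#' @param counts Long-format per-position counts (see
#'   [read_insertion_table()]).
#' @param genes Annotation data.frame (see [read_annotation()]).
#' @param sheet Sample sheet (see [read_sample_sheet()]); every sheet
#'   sample is analysed, samples absent from `counts` are treated as
#'   all-zero profiles.
#' @param config A [pipeline_config()].
#' @return An object of class `"tn_screen"`: a list with
#'   \describe{
#'     \item{results}{wide per-gene table: coordinates, per-sample
#'       `sites_*`, `reads_*`, `freq_*`, per-time `fc_*h`, criteria
#'       flags and `verdict`;}
#'     \item{stats}{long gene x sample statistics;}
#'     \item{fc}{gene x pair fold changes (`by_pair`) and the
#'       replicate-averaged `series`;}
#'     \item{pairs}{the generation-matched sample pairs;}
#'     \item{log}{per-stage record counts;}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_tnseq(sim_config(genome_length = 5e4, n_genes = 20,
#'   n_insertions = 800, depth = 5e4, n_protective = 2, n_detrimental = 2,
#'   n_essential = 1, bottleneck_cells = 1e6, seed = 1))
#' scr <- run_screen(sim$counts, sim$annotation, sim$sheet)
#' table(scr$results$verdict)
#' @export
run_screen <- function(counts, genes, sheet, config = pipeline_config()) {
  validate_pipeline_config(config)
  genes <- validate_annotation(genes)
  sheet <- validate_sample_sheet(sheet)
  assert_columns(counts, c("sample_id", "contig", "position", "count"),
                 "counts")
  samples <- sheet$sample_id
  counts <- counts[counts$sample_id %in% samples, , drop = FALSE]

  log <- list(n_samples = length(samples),
              n_genes = nrow(genes),
              n_positions_raw = nrow(counts))

  filtered <- filter_low_coverage(counts, config$min_reads_per_position)
  log$n_positions_filtered <- nrow(filtered)

  m <- counts_matrix(filtered, samples)
  log$n_union_positions <- nrow(m)
  norm <- quantile_normalize(m)
  # a sample keeps only its own retained positions; zeros filled for the
  # normalization are not re-introduced as insertion sites
  norm[m == 0] <- 0
  key <- attr(m, "key")
  norm_long <- data.frame(
    sample_id = rep(samples, each = nrow(key)),
    contig = rep(key$contig, times = length(samples)),
    position = rep(key$position, times = length(samples)),
    count = as.vector(norm),
    stringsAsFactors = FALSE
  )
  norm_long <- norm_long[norm_long$count > 0, , drop = FALSE]
  attr(norm_long, "samples") <- samples

  stats <- aggregate_genes(norm_long, genes, config, samples = samples)
  pairs <- match_samples(sheet, config$pairing_offset_h)
  log$n_pairs <- nrow(pairs)

  if (nrow(genes) == 0L) {
    fc <- list(by_pair = data.frame(), series = data.frame())
    verdicts <- data.frame(gene_id = character(), length_ok = logical(),
                           control_sites_ok = logical(), fc_ok = logical(),
                           amplified_ok = logical(), verdict = character(),
                           stringsAsFactors = FALSE)
  } else {
    fc <- fold_change_table(stats, pairs, config)
    verdicts <- classify_genes(genes, fc$series, config)
  }
  log$n_hits <- sum(verdicts$verdict %in% c("depleted_hit", "enriched_hit"))

  results <- build_results(genes, stats, fc, verdicts, samples)
  structure(list(results = results, stats = stats, fc = fc, pairs = pairs,
                 log = log, config = config),
            class = "tn_screen")
}

# Wide one-row-per-gene results table.
build_results <- function(genes, stats, fc, verdicts, samples) {
  res <- genes[, c("gene_id", "contig", "start", "end", "strand",
                   "length")]
  if (nrow(genes) == 0L) {
    res$verdict <- character()
    return(res)
  }
  for (s in samples) {
    sub <- stats[stats$sample_id == s, , drop = FALSE]
    idx <- match(res$gene_id, sub$gene_id)
    res[[paste0("sites_", s)]] <- sub$sites[idx]
    res[[paste0("reads_", s)]] <- sub$reads[idx]
    res[[paste0("freq_", s)]] <- sub$frequency[idx]
  }
  times <- sort(unique(fc$series$treated_time_h))
  for (tm in times) {
    sub <- fc$series[abs(fc$series$treated_time_h - tm) < 1e-9, ,
                     drop = FALSE]
    idx <- match(res$gene_id, sub$gene_id)
    res[[sprintf("fc_%gh", tm)]] <- sub$log2_fc[idx]
  }
  idx <- match(res$gene_id, verdicts$gene_id)
  for (col in c("length_ok", "control_sites_ok", "fc_ok", "amplified_ok",
                "verdict")) {
    res[[col]] <- verdicts[[col]][idx]
  }
  rownames(res) <- NULL
  res
}

#' @export
print.tn_screen <- function(x, ...) {
  cat("Tn-seq replication-arrest survival screen\n")
  cat(sprintf("  samples: %d   genes: %d   matched pairs: %d\n",
              x$log$n_samples, x$log$n_genes, x$log$n_pairs))
  cat(sprintf("  positions: %d raw -> %d retained (min %g reads)\n",
              x$log$n_positions_raw, x$log$n_positions_filtered,
              x$config$min_reads_per_position))
  tab <- table(factor(x$results$verdict,
                      levels = c("depleted_hit", "enriched_hit",
                                 "neutral", "excluded")))
  cat(sprintf("  verdicts: %d depleted, %d enriched, %d neutral, %d excluded\n",
              tab["depleted_hit"], tab["enriched_hit"], tab["neutral"],
              tab["excluded"]))
  invisible(x)
}
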