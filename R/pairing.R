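#' Generation-matched treated/control sample pairing
#'
#' The arrested pool loses one division generation during the 1 h
#' treatment, so each treated sample harvested at `t` hours of recovery
#' is compared with the control harvested at `t - offset_h` hours (same
#' replicate): with the default offset of 1 h, treated 4 h pairs with
#' control 3 h, treated 2 h with control 1 h. Pairing is mandatory: a
#' treated sample with no matching control is an error, not silently
#' dropped.
#'
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param offset_h Hours by which the control harvest precedes the
#'   treated harvest; default 1.
#' @return Data.frame `treated_id`, `control_id`, `treated_time_h`,
#'   `control_time_h`, `replicate`, sorted by replicate then treated
#'   time.
#' @examples
#' sheet <- data.frame(
#'   sample_id = c("C1", "C2", "C3", "T2", "T3", "T4"),
#'   condition = rep(c("control", "treated"), each = 3),
#'   time_h = c(1, 2, 3, 2, 3, 4), replicate = 1)
#' match_samples(sheet, 1)
#' @export
match_samples <- function(sheet, offset_h = 1) {
  sheet <- validate_sample_sheet(sheet)
  trt <- sheet[sheet$condition == "treated", , drop = FALSE]
  ctl <- sheet[sheet$condition == "control", , drop = FALSE]
  if (nrow(trt) == 0L) fail("sample sheet contains no treated samples")
  want <- trt$time_h - offset_h
  idx <- mapply(function(tm, rep_) {
    hit <- which(abs(ctl$time_h - tm) < 1e-9 & ctl$replicate == rep_)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }, want, trt$replicate)
  orphan <- is.na(idx)
  if (any(orphan)) {
    fail("treated sample(s) with no control at t - %g h: %s", offset_h,
         paste(trt$sample_id[orphan], collapse = ", "))
  }
  out <- data.frame(
    treated_id = trt$sample_id,
    control_id = ctl$sample_id[idx],
    treated_time_h = trt$time_h,
    control_time_h = ctl$time_h[idx],
    replicate = trt$replicate,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$replicate, out$treated_time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' log2 fold change between treated and control frequencies
#'
#' `log2(treated / control)`, vectorized. With no pseudocount (the
#' default) one-sided zeros keep their sentinels: a zero control with a
#' positive treated frequency gives `+Inf`, the converse `-Inf`, and
#' both zero is undefined
#' (`NA`, serialized as the literal `NA` token).
#'
#' @param treated,control Non-negative numeric vectors (frequencies or
#'   normalized read sums).
#' @param pseudocount Added to both sides before the ratio; default 0.
#' @return Numeric vector of log2 ratios.
#' @examples
#' log2_fold_change(4e-4, 1e-4)  # 2
#' @export
log2_fold_change <- function(treated, control, pseudocount = 0) {
  if (length(treated) != length(control)) {
    fail("treated and control vectors must have equal length")
  }
  if (any(treated < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE)) {
    fail("frequencies must be non-negative")
  }
  t2 <- treated + pseudocount
  c2 <- control + pseudocount
  out <- suppressWarnings(log2(t2 / c2))
  out[t2 == 0 & c2 == 0] <- NA_real_
  out
}

#' Fold-change series for every gene over the matched pairs
#'
#' Joins per-gene, per-sample statistics with the generation-matched
#' pairs and computes one log2 fold change per gene per pair. When the
#' sheet carries several replicates, fold changes are averaged per
#' treated time across replicates (mean of defined values); the
#' single-replicate path is the identity.
#'
#' @param stats Output of [aggregate_genes()].
#' @param pairs Output of [match_samples()].
#' @param config A [pipeline_config()].
#' @return A list with `by_pair` (gene x pair fold changes, including
#'   the treated/control inputs) and `series` (gene x treated time,
#'   replicate-averaged `log2_fc`), both sorted by treated time.
#' @export
fold_change_table <- function(stats, pairs, config = pipeline_config()) {
  assert_columns(stats, c("gene_id", "sample_id", "reads", "sites",
                          "frequency"), "stats")
  value_col <- if (config$frequency_based) "frequency" else "reads"
  genes <- unique(stats$gene_id)
  key <- function(g, s) paste(g, s, sep = "\r")
  stat_key <- key(stats$gene_id, stats$sample_id)
  by_pair <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ti <- match(key(genes, pairs$treated_id[i]), stat_key)
    ci <- match(key(genes, pairs$control_id[i]), stat_key)
    if (anyNA(ti) || anyNA(ci)) {
      fail("stats are missing entries for pair %s / %s",
           pairs$treated_id[i], pairs$control_id[i])
    }
    data.frame(
      gene_id = genes,
      treated_time_h = pairs$treated_time_h[i],
      control_time_h = pairs$control_time_h[i],
      replicate = pairs$replicate[i],
      treated_value = stats[[value_col]][ti],
      control_value = stats[[value_col]][ci],
      control_sites = stats$sites[ci],
      log2_fc = log2_fold_change(stats[[value_col]][ti],
                                 stats[[value_col]][ci],
                                 config$pseudocount),
      stringsAsFactors = FALSE
    )
  }))
  times <- sort(unique(by_pair$treated_time_h))
  series <- expand.grid(gene_id = genes, treated_time_h = times,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gf <- factor(by_pair$gene_id, levels = genes)
  tf <- factor(by_pair$treated_time_h, levels = times)
  mean_def <- tapply(by_pair$log2_fc, list(gf, tf), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  csites <- tapply(by_pair$control_sites, list(gf, tf), mean)
  idx <- cbind(match(series$gene_id, genes),
               match(series$treated_time_h, times))
  series$log2_fc <- as.numeric(mean_def[idx])
  series$control_sites <- as.numeric(csites[idx])
  series <- series[order(series$gene_id, series$treated_time_h), ,
                   drop = FALSE]
  rownames(series) <- NULL
  list(by_pair = by_pair, series = series)
}
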