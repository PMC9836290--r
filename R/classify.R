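#' Classify one gene from its fold-change series
#'
#' A gene is called a hit when all four candidate criteria hold:
#' \enumerate{
#'   \item `length_ok`: gene length strictly greater than
#'     `min_gene_length` (200 bp by default);
#'   \item `control_sites_ok`: strictly more than `min_control_sites`
#'     distinct insertion sites in the control sample of the final
#'     comparison (5 by default) — "insertions" counts unique sites, not
#'     reads;
#'   \item `fc_ok`: `|log2 FC|` strictly greater than `fc_threshold` at
#'     the final treated time (hits are called on magnitude; depletion
#'     and enrichment are both of interest);
#'   \item `amplified_ok`: the change amplifies over time — every
#'     defined fold change in the series shares the sign of the final
#'     one, and the magnitude grew: by default `|log2 FC|` at the final
#'     time is at least that of the earliest defined time point
#'     (`amplified_mode = "endpoint"`). The `"monotone"` and `"strict"`
#'     modes instead require `|log2 FC|` non-decreasing / strictly
#'     increasing at every step; they are stronger but reject genuinely
#'     amplifying genes whose per-step growth is smaller than the
#'     sampling noise of a single time point.
#' }
#' Hits are `depleted_hit` (final FC < 0, gene promotes survival) or
#' `enriched_hit` (final FC > 0, gene detrimental to survival). Genes
#' failing the eligibility criteria (i) or (ii) are `excluded`; eligible
#' genes failing (iii) or (iv) are `neutral`.
#'
#' @param gene One-row annotation data.frame (or list) with `gene_id`
#'   and `length` (or `start`/`end`).
#' @param control_sites Distinct retained insertion sites in the control
#'   of the final pair (replicate-averaged when replicates exist).
#' @param fc_series Data.frame `treated_time_h`, `log2_fc` for this
#'   gene, one row per treated time.
#' @param config A [pipeline_config()].
#' @return One-row data.frame: `gene_id`, the four criteria flags, and
#'   `verdict` in `{depleted_hit, enriched_hit, neutral, excluded}`.
#' @examples
#' g <- data.frame(gene_id = "g", contig = "c", start = 1, end = 900,
#'                 strand = "+")
#' fc <- data.frame(treated_time_h = 2:4, log2_fc = c(0.4, 0.8, 1.2))
#' classify_gene(g, control_sites = 12, fc)$verdict  # enriched_hit
#' @export
classify_gene <- function(gene, control_sites, fc_series,
                          config = pipeline_config()) {
  gene_id <- gene$gene_id
  len <- gene$length %||% (gene$end - gene$start + 1)
  fc_series <- fc_series[order(fc_series$treated_time_h), , drop = FALSE]
  fin <- which(abs(fc_series$treated_time_h - config$final_time_h) < 1e-9)
  if (length(fin) == 0L) {
    fail("gene '%s': no fold-change pair at final time %g h", gene_id,
         config$final_time_h)
  }
  final_fc <- fc_series$log2_fc[fin[1]]

  length_ok <- len > config$min_gene_length
  control_sites_ok <- !is.na(control_sites) &&
    control_sites > config$min_control_sites
  fc_ok <- !is.na(final_fc) && abs(final_fc) > config$fc_threshold
  amplified_ok <- amplified_over_time(fc_series$log2_fc, final_fc,
                                      mode = config$amplified_mode)
  hit <- length_ok && control_sites_ok && fc_ok && amplified_ok
  verdict <- if (hit) {
    if (final_fc < 0) "depleted_hit" else "enriched_hit"
  } else if (!length_ok || !control_sites_ok) {
    "excluded"
  } else {
    "neutral"
  }
  data.frame(gene_id = gene_id, length_ok = length_ok,
             control_sites_ok = control_sites_ok, fc_ok = fc_ok,
             amplified_ok = amplified_ok, verdict = verdict,
             stringsAsFactors = FALSE)
}

# Criterion (iv): defined fold changes are sign-consistent with the final
# one and |FC| grew over the series. "endpoint" compares last vs first
# defined |FC| (>=); "monotone"/"strict" require every step to be
# non-decreasing / strictly increasing. Inf-to-Inf steps count as equal.
amplified_over_time <- function(fcs, final_fc,
                                mode = c("endpoint", "monotone",
                                         "strict")) {
  mode <- match.arg(mode)
  if (is.na(final_fc)) return(FALSE)
  def <- fcs[!is.na(fcs)]
  if (length(def) == 0L) return(FALSE)
  sgn <- sign(final_fc)
  if (!all(sign(def) == sgn)) return(FALSE)
  a <- abs(def)
  if (mode == "endpoint") {
    last <- a[length(a)]
    return(last >= a[1] || (is.infinite(last) && is.infinite(a[1])))
  }
  d <- diff(a)
  inf_step <- is.nan(d)  # Inf - Inf: already maximal, treat as equal
  d <- d[!inf_step]
  if (mode == "strict") all(d > 0) else all(d >= 0)
}

#' Classify every gene of a screen
#'
#' Vectorized driver over [classify_gene()]'s rule, applied to the
#' replicate-averaged fold-change series of all genes.
#'
#' @param genes Annotation data.frame.
#' @param series The `series` element of [fold_change_table()] (columns
#'   `gene_id`, `treated_time_h`, `log2_fc`, `control_sites`).
#' @param config A [pipeline_config()].
#' @return Data.frame with one row per gene: criteria flags and verdict.
#' @export
classify_genes <- function(genes, series, config = pipeline_config()) {
  genes <- validate_annotation(genes)
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), length_ok = logical(),
                      control_sites_ok = logical(), fc_ok = logical(),
                      amplified_ok = logical(), verdict = character(),
                      stringsAsFactors = FALSE))
  }
  fin_sel <- abs(series$treated_time_h - config$final_time_h) < 1e-9
  if (!any(fin_sel)) {
    fail("fold-change series has no pair at final time %g h",
         config$final_time_h)
  }
  split_series <- split(series[, c("treated_time_h", "log2_fc")],
                        series$gene_id)
  final_sites <- setNames(series$control_sites[fin_sel],
                          series$gene_id[fin_sel])
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    classify_gene(genes[i, , drop = FALSE], final_sites[[gid]],
                  split_series[[gid]], config)
  }))
  rownames(out) <- NULL
  out
}
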