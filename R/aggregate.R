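#' Internal scoring window of a gene
#'
#' Insertions in the extremities of a gene are sometimes tolerated even
#' when the gene is essential, so only the central 5--95% of each gene is
#' scored by default. The window is computed on genomic coordinates
#' (strand-independent): `win_start = start + floor(lower * L)` and
#' `win_end = end - floor((1 - upper) * L)` with `L = end - start + 1`,
#' both 1-based inclusive. For very short genes the window can be empty
#' (`win_start > win_end`), flagged in the `empty` column.
#'
#' @param genes Annotation data.frame (or a single-row subset).
#' @param lower,upper Window fractions, `0 <= lower < upper <= 1`.
#' @return Data.frame `gene_id`, `win_start`, `win_end`, `empty`.
#' @examples
#' g <- data.frame(gene_id = "g", contig = "c", start = 1, end = 1000,
#'                 strand = "+")
#' internal_window(g, 0.05, 0.95)  # 51..950
#' @export
internal_window <- function(genes, lower = 0.05, upper = 0.95) {
  if (!(lower >= 0 && upper <= 1 && lower < upper)) {
    fail("window fractions must satisfy 0 <= lower < upper <= 1")
  }
  genes <- validate_annotation(genes)
  L <- genes$length
  # tiny epsilon guards against floating-point noise at exact multiples
  win_start <- genes$start + floor(lower * L + 1e-9)
  win_end <- genes$end - floor((1 - upper) * L + 1e-9)
  data.frame(gene_id = genes$gene_id,
             win_start = as.integer(win_start),
             win_end = as.integer(win_end),
             empty = win_start > win_end,
             stringsAsFactors = FALSE)
}

#' Aggregate normalized insertion counts per gene and sample
#'
#' For each gene and sample, sums the (filtered, normalized) reads at
#' positions inside the gene's internal window, counts the distinct
#' retained insertion sites there, and expresses the read sum as a
#' genome-wide frequency (divided by the sample's total retained
#' normalized reads, including intergenic positions). A position falling
#' in the windows of several overlapping genes is counted for every one
#' of them. Genes on contigs absent from a sample, or with empty
#' windows, score `reads = 0, sites = 0`.
#'
#' @param counts Long-format counts, already filtered and normalized;
#'   rows are the retained insertion sites of each sample.
#' @param genes Annotation data.frame.
#' @param config A [pipeline_config()] (window fractions are taken from
#'   it).
#' @param samples Full ordered sample set; defaults to the `"samples"`
#'   attribute or the samples present.
#' @return Data.frame `gene_id`, `sample_id`, `reads`, `sites`,
#'   `frequency` over the full gene x sample grid.
#' @export
aggregate_genes <- function(counts, genes, config = pipeline_config(),
                            samples = NULL) {
  assert_columns(counts, c("sample_id", "contig", "position", "count"),
                 "counts")
  genes <- validate_annotation(genes)
  samples <- samples %||% attr(counts, "samples") %||%
    unique(counts$sample_id)
  grid <- expand.grid(gene_id = genes$gene_id, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$reads <- numeric(nrow(grid))
  grid$sites <- integer(nrow(grid))
  grid$frequency <- numeric(nrow(grid))
  if (nrow(genes) == 0L || length(samples) == 0L) return(grid)

  totals <- setNames(numeric(length(samples)), samples)
  if (nrow(counts) > 0L) {
    by_sample <- tapply(counts$count, factor(counts$sample_id, samples), sum)
    totals[!is.na(by_sample)] <- by_sample[!is.na(by_sample)]

    win <- internal_window(genes, config$window_lower, config$window_upper)
    live <- which(!win$empty)
    if (length(live) > 0L) {
      gr_win <- GenomicRanges::GRanges(
        seqnames = genes$contig[live],
        ranges = IRanges::IRanges(win$win_start[live], win$win_end[live])
      )
      gr_pos <- GenomicRanges::GRanges(
        seqnames = counts$contig,
        ranges = IRanges::IRanges(counts$position, width = 1L)
      )
      ov <- suppressWarnings(
        GenomicRanges::findOverlaps(gr_pos, gr_win, ignore.strand = TRUE)
      )
      if (length(ov) > 0L) {
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        gene_f <- factor(genes$gene_id[live][sh], levels = genes$gene_id)
        sample_f <- factor(counts$sample_id[qh], levels = samples)
        reads <- tapply(counts$count[qh], list(gene_f, sample_f), sum)
        sites <- table(gene_f, sample_f)
        idx <- cbind(match(grid$gene_id, genes$gene_id),
                     match(grid$sample_id, samples))
        r <- reads[idx]
        grid$reads <- ifelse(is.na(r), 0, r)
        grid$sites <- as.integer(sites[idx])
      }
    }
  }
  tot <- totals[grid$sample_id]
  grid$frequency <- ifelse(tot > 0, grid$reads / tot, 0)
  grid
}
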