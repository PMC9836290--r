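#' Discard low-coverage insertion positions
#'
#' Positions supported by fewer than `min_reads` reads in a sample are
#' removed from that sample's sparse profile (strict `<`; a position with
#' exactly `min_reads` reads is retained). Rare or misaligned reads at a
#' genuine insertion site produce spurious one- and two-read positions;
#' this filter removes them before normalization.
#'
#' @param counts Long-format counts (`sample_id`, `contig`, `position`,
#'   `count`).
#' @param min_reads Non-negative threshold; default 3.
#' @return The filtered counts, same columns, input row order preserved.
#' @examples
#' x <- data.frame(sample_id = "A", contig = "chr1",
#'                 position = c(100, 200, 300), count = c(2, 3, 10))
#' filter_low_coverage(x, 3)
#' @export
filter_low_coverage <- function(counts, min_reads = 3) {
  assert_columns(counts, c("sample_id", "contig", "position", "count"),
                 "counts")
  if (!is.numeric(min_reads) || length(min_reads) != 1L || min_reads < 0) {
    fail("min_reads must be a non-negative number")
  }
  out <- counts[counts$count >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(counts, "samples")
  out
}

#' Inter-sample quantile normalization
#'
#' Forces every sample's value distribution to the common distribution of
#' across-sample rank means: each sample is sorted, the mean at each rank
#' across samples is computed, and values are reassigned by rank. Tied
#' values within a sample receive the mean of the rank means their ranks
#' span. After normalization every sample's sorted vector (and hence its
#' total) is identical, while within-sample rank order is preserved.
#'
#' The matrix method normalizes columns. The data.frame method takes
#' sparse long-format counts, builds the dense matrix over the union of
#' positions present in any sample (absent positions contribute 0), and
#' returns dense long output over that union for every sample.
#'
#' @param x Numeric matrix (positions x samples) or long-format counts.
#' @param samples For the data.frame method: the full ordered sample set
#'   (defaults to the `"samples"` attribute or the samples present).
#' @return Same shape as the input, normalized values.
#' @examples
#' m <- cbind(A = c(5, 2, 3), B = c(4, 1, 2))
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(x, samples = NULL) {
  UseMethod("quantile_normalize")
}

#' @rdname quantile_normalize
#' @export
quantile_normalize.matrix <- function(x, samples = NULL) {
  if (ncol(x) == 0L || nrow(x) == 0L) return(x)
  if (anyNA(x)) fail("quantile normalization input must not contain NA")
  sorted <- apply(x, 2L, sort.int, method = "quick")
  if (nrow(x) == 1L) sorted <- matrix(sorted, nrow = 1L)
  mu <- rowMeans(sorted)
  cmu <- c(0, cumsum(mu))
  out <- x
  for (j in seq_len(ncol(x))) {
    rmin <- rank(x[, j], ties.method = "min")
    rmax <- rank(x[, j], ties.method = "max")
    # mean of the rank means spanned by each (possibly tied) value
    out[, j] <- (cmu[rmax + 1L] - cmu[rmin]) / (rmax - rmin + 1L)
  }
  out
}

#' @rdname quantile_normalize
#' @export
quantile_normalize.data.frame <- function(x, samples = NULL) {
  assert_columns(x, c("sample_id", "contig", "position", "count"), "counts")
  samples <- samples %||% attr(x, "samples") %||% unique(x$sample_id)
  if (length(samples) == 0L) {
    fail("quantile normalization requires at least one sample")
  }
  m <- counts_matrix(x, samples)
  norm <- quantile_normalize.matrix(m)
  key <- attr(m, "key")
  out <- data.frame(
    sample_id = rep(samples, each = nrow(key)),
    contig = rep(key$contig, times = length(samples)),
    position = rep(key$position, times = length(samples)),
    count = as.vector(norm),
    stringsAsFactors = FALSE
  )
  attr(out, "samples") <- samples
  out
}

# Dense matrix (union positions x samples) from sparse long counts.
# Rows are ordered by (contig, position); the key data.frame is attached
# as attribute "key".
counts_matrix <- function(counts, samples) {
  key <- unique(data.frame(contig = as.character(counts$contig),
                           position = as.integer(counts$position),
                           stringsAsFactors = FALSE))
  key <- key[order(key$contig, key$position), , drop = FALSE]
  rownames(key) <- NULL
  m <- matrix(0, nrow = nrow(key), ncol = length(samples),
              dimnames = list(NULL, samples))
  if (nrow(counts) > 0L) {
    ri <- match(paste(counts$contig, counts$position),
                paste(key$contig, key$position))
    ci <- match(counts$sample_id, samples)
    keep <- !is.na(ci)
    m[cbind(ri[keep], ci[keep])] <- counts$count[keep]
  }
  attr(m, "key") <- key
  m
}
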