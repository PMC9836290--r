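# Brute-force quantile-normalization oracle, independent of the package
# implementation: explicit sort / rank-mean / reassign, walking tie groups
# by value and averaging the rank means they span.
qn_oracle <- function(m) {
  n <- nrow(m)
  sorted <- sapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  if (n == 1L) sorted <- matrix(sorted, nrow = 1L)
  mu <- rowMeans(as.matrix(sorted))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ord <- order(x)
    res <- numeric(n)
    i <- 1L
    while (i <= n) {
      k <- i
      while (k < n && x[ord[k + 1L]] == x[ord[i]]) k <- k + 1L
      res[ord[i:k]] <- mean(mu[i:k])
      i <- k + 1L
    }
    out[, j] <- res
  }
  out
}

random_count_matrix <- function(nr, nc, max_count = 50, zero_frac = 0.2) {
  m <- matrix(rpois(nr * nc, lambda = runif(1, 1, max_count)), nr, nc)
  m[runif(nr * nc) < zero_frac] <- 0L
  m
}

# Long-format counts from a wide matrix (positions x samples), dropping
# zeros; positions spaced 10 bp on chr1 unless given.
long_counts <- function(m, samples = colnames(m),
                        positions = seq_len(nrow(m)) * 10L,
                        contig = "chr1") {
  stopifnot(!is.null(samples))
  idx <- which(m > 0, arr.ind = TRUE)
  out <- data.frame(sample_id = samples[idx[, 2]],
                    contig = contig,
                    position = positions[idx[, 1]],
                    count = as.numeric(m[idx]),
                    stringsAsFactors = FALSE)
  attr(out, "samples") <- samples
  out
}

golden_path <- function(file) {
  system.file("extdata", "golden", file, package = "tnscreen",
              mustWork = TRUE)
}

# Small deterministic simulation for integration tests.
small_sim_config <- function(seed = 1, ...) {
  args <- list(genome_length = 1e5, n_genes = 40, n_insertions = 2000,
               depth = 1e5, bottleneck_cells = 2e6, n_protective = 3,
               n_detrimental = 3, n_essential = 2, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
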