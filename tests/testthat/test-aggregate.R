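test_that("internal window follows the floor rule on both margins", {
  g <- function(start, end) {
    data.frame(gene_id = "g", contig = "c", start = start, end = end,
               strand = "+")
  }
  w <- internal_window(g(1, 1000), 0.05, 0.95)
  expect_equal(c(w$win_start, w$win_end), c(51L, 950L))

  w <- internal_window(g(101, 120), 0.05, 0.95)  # L = 20, floor(1) = 1
  expect_equal(c(w$win_start, w$win_end), c(102L, 119L))

  w <- internal_window(g(37, 444), 0, 1)
  expect_equal(c(w$win_start, w$win_end), c(37L, 444L))

  expect_error(internal_window(g(1, 10), 0.5, 0.5), "lower < upper")
})

test_that("window is inside the gene with length within 1 bp of target", {
  set.seed(3)
  lens <- c(1:50, sample(51:10000, 150))
  genes <- data.frame(gene_id = paste0("g", seq_along(lens)),
                      contig = "c", start = 1000L,
                      end = 1000L + lens - 1L, strand = "+")
  for (frac in list(c(0.05, 0.95), c(0.1, 0.9), c(0.25, 0.6))) {
    w <- internal_window(genes, frac[1], frac[2])
    live <- !w$empty
    expect_true(all(w$win_start[live] >= genes$start[live]))
    expect_true(all(w$win_end[live] <= genes$end[live]))
    # each margin floors independently, so the window exceeds the target
    # fraction by strictly less than 2 bp and never undershoots it
    wl <- w$win_end - w$win_start + 1
    target <- (frac[2] - frac[1]) * lens
    dev <- wl[live] - target[live]
    expect_true(all(dev >= -1e-9 & dev < 2))
  }
})

test_that("gene aggregation applies the window and totals", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", start = 1L,
                      end = 1000L, strand = "+")
  counts <- data.frame(sample_id = "A", contig = "chr1",
                       position = c(40L, 100L, 960L), count = c(7, 5, 9))
  st <- aggregate_genes(counts, genes, samples = "A")
  # window is (51, 950): 40 and 960 fall outside
  expect_equal(st$reads, 5)
  expect_equal(st$sites, 1L)
  expect_equal(st$frequency, 5 / 21)

  # contig absent from the profile: zero stats, not an error
  far <- data.frame(sample_id = "A", contig = "chr9",
                    position = 100L, count = 5)
  st2 <- aggregate_genes(far, genes, samples = "A")
  expect_equal(st2$reads, 0)
  expect_equal(st2$sites, 0L)

  # all counts inside the window: plain sum and entry count
  inside <- data.frame(sample_id = "A", contig = "chr1",
                       position = c(100L, 200L, 300L), count = c(1, 2, 4))
  st3 <- aggregate_genes(inside, genes, samples = "A")
  expect_equal(st3$reads, 7)
  expect_equal(st3$sites, 3L)
  expect_equal(st3$frequency, 1)
})

test_that("positions in overlapping genes count for every gene", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                      start = c(1L, 500L), end = c(1000L, 1400L),
                      strand = "+")
  counts <- data.frame(sample_id = "A", contig = "chr1",
                       position = c(600L, 1200L), count = c(3, 5))
  st <- aggregate_genes(counts, genes, samples = "A")
  expect_equal(st$reads[st$gene_id == "g1"], 3)
  expect_equal(st$reads[st$gene_id == "g2"], 8)
  # sites = reads = 0 coupling and frequency cap
  expect_true(all((st$sites == 0) == (st$reads == 0)))
  expect_lte(sum(st$frequency), 8 / 8 + 1)
})

test_that("frequencies over one sample's genes never exceed one", {
  set.seed(23)
  n <- 30
  len <- sample(200:1500, n)
  gap <- sample(20:200, n)
  start <- cumsum(gap) + cumsum(c(0, len[-n]))
  genes <- data.frame(gene_id = paste0("g", 1:n), contig = "chr1",
                      start = as.integer(start),
                      end = as.integer(start + len - 1L), strand = "+")
  m <- random_count_matrix(500, 3)
  colnames(m) <- c("a", "b", "c")
  counts <- long_counts(m, positions = sort(sample(1:60000, 500)))
  st <- aggregate_genes(counts, genes)
  for (s in c("a", "b", "c")) {
    expect_lte(sum(st$frequency[st$sample_id == s]), 1 + 1e-12)
  }
  expect_true(all((st$sites == 0) == (st$reads == 0)))
})
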