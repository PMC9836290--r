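gene_of_length <- function(len, id = "g") {
  data.frame(gene_id = id, contig = "c", start = 1L, end = as.integer(len),
             strand = "+")
}

series_of <- function(...) {
  fc <- c(...)
  data.frame(treated_time_h = seq(4 - length(fc) + 1, 4), log2_fc = fc)
}

test_that("the four candidate criteria gate the verdict", {
  cfg <- pipeline_config()

  # short gene: excluded regardless of a huge fold change
  v <- classify_gene(gene_of_length(150), 20, series_of(2, 4, 8), cfg)
  expect_false(v$length_ok)
  expect_equal(v$verdict, "excluded")

  # too few control insertion sites
  v <- classify_gene(gene_of_length(900), 4, series_of(2, 4, 8), cfg)
  expect_false(v$control_sites_ok)
  expect_equal(v$verdict, "excluded")

  # all criteria pass, positive FC: insertions enriched
  v <- classify_gene(gene_of_length(900), 12, series_of(0.4, 0.8, 1.2),
                     cfg)
  expect_true(all(unlist(v[c("length_ok", "control_sites_ok", "fc_ok",
                             "amplified_ok")])))
  expect_equal(v$verdict, "enriched_hit")

  # shrinking magnitude: fold change fails the amplification criterion
  v <- classify_gene(gene_of_length(900), 12, series_of(1.5, 1.2, 1.1),
                     cfg)
  expect_true(v$fc_ok)
  expect_false(v$amplified_ok)
  expect_equal(v$verdict, "neutral")

  # deep depletion like polA: depleted hit
  v <- classify_gene(gene_of_length(900), 12,
                     series_of(-2.0, -3.1, -6.5), cfg)
  expect_equal(v$verdict, "depleted_hit")

  # sign flip along the series breaks amplification
  v <- classify_gene(gene_of_length(900), 12, series_of(0.3, -1.1, -2),
                     cfg)
  expect_false(v$amplified_ok)

  # undefined final FC cannot be a hit
  v <- classify_gene(gene_of_length(900), 12, series_of(1, 2, NA), cfg)
  expect_false(v$fc_ok)
  expect_false(v$amplified_ok)
  expect_equal(v$verdict, "neutral")

  expect_error(
    classify_gene(gene_of_length(900), 12,
                  data.frame(treated_time_h = 2, log2_fc = 1), cfg),
    "final time")
})

test_that("thresholds are strict at their boundary values", {
  cfg <- pipeline_config()
  # length exactly 200 bp is not "longer than 200 bp"
  v <- classify_gene(gene_of_length(200), 20, series_of(1.5, 2, 3), cfg)
  expect_false(v$length_ok)
  v <- classify_gene(gene_of_length(201), 20, series_of(1.5, 2, 3), cfg)
  expect_true(v$length_ok)

  # exactly 5 control sites is not "more than 5 insertions"
  v <- classify_gene(gene_of_length(900), 5, series_of(1.5, 2, 3), cfg)
  expect_false(v$control_sites_ok)
  v <- classify_gene(gene_of_length(900), 6, series_of(1.5, 2, 3), cfg)
  expect_true(v$control_sites_ok)

  # |FC| exactly 1 fails the strict threshold, in both directions
  v <- classify_gene(gene_of_length(900), 12, series_of(0.2, 0.5, 1.0),
                     cfg)
  expect_false(v$fc_ok)
  expect_equal(v$verdict, "neutral")
  v <- classify_gene(gene_of_length(900), 12,
                     series_of(-0.2, -0.5, -1.0), cfg)
  expect_false(v$fc_ok)
  v <- classify_gene(gene_of_length(900), 12,
                     series_of(-0.2, -0.5, -1.0001), cfg)
  expect_true(v$fc_ok)
})

test_that("amplification modes: endpoint vs per-step monotone", {
  g <- gene_of_length(900)
  wobble <- series_of(2.2, 3.4, 3.0)  # grew overall, dipped at one step
  expect_equal(classify_gene(g, 12, wobble,
                             pipeline_config())$verdict, "enriched_hit")
  expect_equal(
    classify_gene(g, 12, wobble,
                  pipeline_config(amplified_mode = "monotone"))$verdict,
    "neutral")
  flat_end <- series_of(1.4, 1.4, 1.4)
  expect_true(classify_gene(g, 12, flat_end,
                            pipeline_config())$amplified_ok)
  expect_false(
    classify_gene(g, 12, flat_end,
                  pipeline_config(amplified_mode = "strict"))$amplified_ok)

  # one-sided zero controls: +Inf series still classifies
  inf_series <- series_of(2, Inf, Inf)
  expect_equal(classify_gene(g, 12, inf_series,
                             pipeline_config())$verdict, "enriched_hit")
})

test_that("raising the final |FC| never turns a hit into a non-hit", {
  cfg <- pipeline_config()
  g <- gene_of_length(900)
  set.seed(41)
  for (i in 1:30) {
    base <- sort(abs(rnorm(3, 1, 1.5))) * sample(c(-1, 1), 1)
    v0 <- classify_gene(g, 12, series_of(base[1], base[2], base[3]), cfg)
    if (!v0$verdict %in% c("depleted_hit", "enriched_hit")) next
    for (scale in c(1.5, 3, 10)) {
      v1 <- classify_gene(g, 12,
                          series_of(base[1], base[2], base[3] * scale),
                          cfg)
      expect_equal(v1$verdict, v0$verdict)
    }
  }
})
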