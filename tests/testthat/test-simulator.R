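test_that("simulated annotations tile without overlap, reproducibly", {
  cfg <- small_sim_config(seed = 2)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), cfg$n_genes)
  expect_true(all(ann$length >= cfg$gene_length_min))
  expect_true(all(ann$end <= cfg$genome_length))
  expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))  # no overlap
  expect_identical(ann, simulate_annotation(cfg))

  expect_equal(nrow(simulate_annotation(sim_config(n_genes = 0))), 0L)
  expect_error(
    simulate_annotation(sim_config(genome_length = 1e4, n_genes = 50,
                                   seed = 1)),
    "cannot fit")
})

test_that("libraries avoid essential internal windows and reproduce", {
  cfg <- small_sim_config(seed = 3)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  expect_equal(sort(unique(truth$class)),
               c("detrimental", "essential", "neutral", "protective"))
  lib <- simulate_library(ann, truth, cfg)
  expect_equal(nrow(lib), cfg$n_insertions)
  expect_false(any(duplicated(lib$position)))
  ess <- ann[ann$gene_id %in% truth$gene_id[truth$class == "essential"], ]
  win <- internal_window(ess, cfg$window_lower, cfg$window_upper)
  for (i in seq_len(nrow(win))) {
    expect_false(any(lib$position >= win$win_start[i] &
                       lib$position <= win$win_end[i]))
  }
  expect_identical(lib, simulate_library(ann, truth, cfg))
  expect_error(
    simulate_library(ann, truth,
                     small_sim_config(seed = 3, n_insertions = 2e5)),
    "exceeds")
})

test_that("TA-restricted libraries only insert at TA dinucleotides", {
  cfg <- small_sim_config(seed = 4, ta_restricted = TRUE,
                          n_insertions = 500)
  ann <- simulate_annotation(cfg)
  lib <- simulate_library(ann, NULL, cfg)
  genome <- attr(lib, "genome")
  expect_s4_class(genome, "DNAString")
  dinuc <- vapply(lib$position, function(p) {
    as.character(Biostrings::subseq(genome, p, p + 1L))
  }, character(1))
  expect_true(all(dinuc == "TA"))
})

test_that("each sample's reads sum exactly to the sequencing depth", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_tnseq(cfg)
  by_sample <- tapply(sim$counts$count, sim$counts$sample_id, sum)
  expect_true(all(by_sample == cfg$depth))

  zero <- simulate_experiment(sim$library, sim$truth,
                              small_sim_config(seed = 5, depth = 0))
  expect_equal(nrow(zero$counts), 0L)
  expect_equal(nrow(zero$sheet), 7L)
})

test_that("bottleneck survivors never exceed pre-arrest clone counts", {
  sim <- simulate_tnseq(small_sim_config(seed = 6))
  bn <- sim$bottleneck
  expect_true(all(bn$survivors <= bn$cells))
  expect_true(all(bn$survivors >= 0))
  expect_true(all(sim$library$abundance > 0))
})

test_that("a gene with zero survival yields no treated reads", {
  cfg <- small_sim_config(seed = 8)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  dead <- truth$gene_id[truth$class == "protective"][1]
  truth$survival[truth$gene_id == dead] <- 0
  lib <- simulate_library(ann, truth, cfg)
  expt <- simulate_experiment(lib, truth, cfg)
  dead_pos <- lib$position[lib$gene_id %in% dead]
  trt <- expt$counts[grepl("^trt", expt$counts$sample_id), ]
  expect_false(any(trt$position %in% dead_pos))
  ctl <- expt$counts[grepl("^ctl", expt$counts$sample_id), ]
  expect_true(any(ctl$position %in% dead_pos))
})

test_that("larger planted survival effects give larger fold changes", {
  fc_of_factor <- function(fac, seed) {
    cfg <- small_sim_config(seed = seed, n_protective = 4,
                            n_detrimental = 0, n_essential = 0,
                            protective_survival_factor = fac)
    sim <- simulate_tnseq(cfg)
    scr <- run_screen(sim$counts, sim$annotation, sim$sheet)
    prot <- sim$truth$gene_id[sim$truth$class == "protective"]
    mean(scr$results$fc_4h[scr$results$gene_id %in% prot])
  }
  for (seed in 1:3) {
    weak <- fc_of_factor(0.5, seed)
    strong <- fc_of_factor(0.05, seed)
    expect_lt(strong, weak)   # deeper survival deficit, deeper depletion
    expect_lt(weak, 0)
  }
})

test_that("recovery evaluation scores hits, signs and universes", {
  truth <- data.frame(
    gene_id = paste0("g", 1:6),
    class = c("protective", "detrimental", "neutral", "neutral",
              "essential", "neutral"))
  results <- data.frame(
    gene_id = paste0("g", 1:6),
    verdict = c("depleted_hit", "enriched_hit", "neutral", "neutral",
                "excluded", "neutral"))
  ev <- evaluate_recovery(results, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$sign_accuracy, 1)

  # all-neutral verdicts: nothing recovered
  none <- results
  none$verdict <- "neutral"
  ev0 <- evaluate_recovery(none, truth)
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$sign_accuracy))

  # planted detrimental called depleted: a sign error, not a recovery
  flipped <- results
  flipped$verdict[2] <- "depleted_hit"
  ev1 <- evaluate_recovery(flipped, truth)
  expect_equal(ev1$sensitivity, 0.5)
  expect_equal(ev1$sign_accuracy, 0.5)

  expect_error(evaluate_recovery(results[-1, ], truth), "universe")
})
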