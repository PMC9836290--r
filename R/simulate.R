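#' Simulation configuration
#'
#' Parameters of the synthetic insertion-library generator. The defaults
#' are a scaled-down screen — 500 kb genome, 200 genes, 10^4 unique
#' insertion sites, 5x10^5 reads per sample — that preserves the real
#' screen's per-gene insertion density (~18 sites in a 900 bp gene, one
#' site per 50 bp) while keeping simulation runtimes small.
#' [sim_config_fullscale()] gives full-scale parameters matching the
#' saturated mariner library (10^5 sites, one insertion per 37 bp).
#'
#' @param genome_length Genome size in bp. If `NULL`, derived from the
#'   expected genic bp and `intergenic_fraction`.
#' @param n_genes Number of genes tiled on the genome.
#' @param gene_length_mean,gene_length_sd,gene_length_min Gene-length
#'   distribution (normal, truncated below at the minimum), in bp.
#' @param intergenic_fraction Target fraction of the genome outside
#'   genes; only used to derive `genome_length` when that is `NULL`.
#' @param n_insertions Number of unique insertion sites in the founding
#'   library.
#' @param ta_restricted If `TRUE`, a genome sequence is generated and
#'   insertion sites are restricted to TA dinucleotides
#'   (mariner-transposon target sites); off by default, the analysis is
#'   sequence-agnostic.
#' @param gc_content GC fraction of the generated sequence (used only
#'   when `ta_restricted`).
#' @param depth Sequencing reads per sample.
#' @param generations_control Control-pool division generations per hour
#'   of recovery; the treated pool lags by exactly one hour's worth.
#' @param bottleneck_cells Population size at the survival bottleneck.
#' @param abundance_sdlog Log-normal sd of founding clone abundances.
#' @param s0 Baseline (wild-type-like) probability that a clone survives
#'   the 1 h arrest.
#' @param n_protective,n_detrimental,n_essential Numbers of planted
#'   genes per class.
#' @param protective_survival_factor,detrimental_survival_factor
#'   Multiplier on `s0` for planted mutants (protective-gene mutants
#'   survive worse: factor < 1; detrimental-gene mutants better:
#'   factor > 1, capped at survival 1).
#' @param protective_growth,detrimental_growth Relative growth rate per
#'   generation of planted mutants during recovery of the *treated*
#'   pool (1 = baseline). Encodes that a mutant's arrest phenotype
#'   continues during recovery, which is what makes its fold change
#'   amplify over time.
#' @param min_plant_length Minimum length (bp) of genes eligible for
#'   planting effects.
#' @param treated_times,control_times Harvest times (hours of recovery).
#' @param dispersion Optional per-site gamma over-dispersion of read
#'   sampling (0 = pure multinomial).
#' @param window_lower,window_upper Internal-window fractions used to
#'   keep essential genes free of insertions.
#' @param n_replicates Libraries per condition/time (a typical
#'   screen has one).
#' @param seed Integer seed; stage seeds are derived from it.
#' @return Named list of class `"tn_sim_config"`.
#' @export
sim_config <- function(genome_length = 5e5,
                       n_genes = 200,
                       gene_length_mean = 900,
                       gene_length_sd = 250,
                       gene_length_min = 150,
                       intergenic_fraction = NULL,
                       n_insertions = 1e4,
                       ta_restricted = FALSE,
                       gc_content = 0.435,
                       depth = 5e5,
                       generations_control = 1,
                       bottleneck_cells = 1e7,
                       abundance_sdlog = 1,
                       s0 = 0.05,
                       n_protective = 10,
                       n_detrimental = 10,
                       n_essential = 10,
                       protective_survival_factor = 0.1,
                       detrimental_survival_factor = 10,
                       protective_growth = 0.5,
                       detrimental_growth = 1.5,
                       min_plant_length = 250,
                       treated_times = c(2, 3, 4),
                       control_times = c(1, 2, 3, 4),
                       dispersion = 0,
                       window_lower = 0.05,
                       window_upper = 0.95,
                       n_replicates = 1,
                       seed = NULL) {
  if (is.null(genome_length)) {
    if (is.null(intergenic_fraction) || intergenic_fraction < 0 ||
        intergenic_fraction >= 1) {
      fail("intergenic_fraction in [0, 1) is required to derive genome_length")
    }
    genome_length <- ceiling(n_genes * gene_length_mean /
                               (1 - intergenic_fraction))
  }
  cfg <- as.list(environment())
  for (f in c("genome_length", "n_genes", "n_insertions", "depth",
              "bottleneck_cells", "gene_length_min", "n_replicates")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      fail("sim config field '%s' must be non-negative", f)
    }
  }
  if (cfg$s0 <= 0 || cfg$s0 > 1) fail("s0 must be in (0, 1]")
  class(cfg) <- c("tn_sim_config", "list")
  cfg
}

#' Full-scale simulation preset
#'
#' Parameters at realistic screen scale: 10^5 unique
#' insertion sites on a 3.7 Mb effective genome (one insertion per
#' 37 bp), ~3700 genes of mean length 900 bp (~90% coding).
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_fullscale <- function(...) {
  sim_config(genome_length = 3.7e6, n_genes = 3700, n_insertions = 1e5,
             depth = 5e6, bottleneck_cells = 1e8, n_essential = 220, ...)
}

#' Simulate a gene annotation
#'
#' Tiles `n_genes` non-overlapping genes (normal lengths, truncated at
#' the minimum) along a single contig, with the leftover bp distributed
#' multinomially over the `n_genes + 1` intergenic gaps (each at least
#' 1 bp). Reproducible under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Annotation data.frame (see [read_annotation()]).
#' @export
simulate_annotation <- function(config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    n <- config$n_genes
    if (n == 0L) return(empty_annotation())
    len <- pmax(round(rnorm(n, config$gene_length_mean,
                            config$gene_length_sd)),
                config$gene_length_min)
    spare <- config$genome_length - sum(len) - (n + 1L)
    if (spare < 0) {
      fail("genes cannot fit: %d genic bp + minimal gaps exceed genome of %d bp",
           sum(len), as.integer(config$genome_length))
    }
    gaps <- as.vector(rmultinom(1, spare, rep(1, n + 1L))) + 1L
    start <- cumsum(c(0, len[-n])) + cumsum(gaps[-(n + 1L)])
    ann <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n)),
      contig = "chr1",
      start = as.integer(start + 1L),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    validate_annotation(ann)
  })
}

#' Plant per-gene fitness effects
#'
#' Assigns each gene a class (`neutral`, `protective`, `detrimental`,
#' `essential`), a survival probability through the arrest bottleneck
#' and a relative growth rate during treated-pool recovery. Protective
#' genes (their mutants die more: survival `s0 *
#' protective_survival_factor`, slowed recovery) are expected to be
#' depleted; detrimental genes the opposite. Effects are planted only in
#' genes longer than `min_plant_length` so every planted effect is
#' detectable in principle.
#'
#' @param annotation Annotation data.frame.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data.frame `gene_id`, `class`, `survival`, `growth` (one row
#'   per gene).
#' @export
simulate_truth <- function(annotation, config = sim_config(), seed = NULL) {
  annotation <- validate_annotation(annotation)
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    truth <- data.frame(gene_id = annotation$gene_id,
                        class = "neutral",
                        survival = config$s0,
                        growth = 1,
                        stringsAsFactors = FALSE)
    n_plant <- config$n_protective + config$n_detrimental +
      config$n_essential
    eligible <- which(annotation$length > config$min_plant_length)
    if (n_plant > length(eligible)) {
      fail("cannot plant %d effects: only %d genes longer than %d bp",
           n_plant, length(eligible), as.integer(config$min_plant_length))
    }
    picked <- sample(eligible, n_plant)
    i <- 0L
    take <- function(k) {
      out <- picked[seq_len(k) + i]
      i <<- i + k
      out
    }
    prot <- take(config$n_protective)
    detr <- take(config$n_detrimental)
    ess <- take(config$n_essential)
    truth$class[prot] <- "protective"
    truth$survival[prot] <- config$s0 * config$protective_survival_factor
    truth$growth[prot] <- config$protective_growth
    truth$class[detr] <- "detrimental"
    truth$survival[detr] <- min(1, config$s0 *
                                  config$detrimental_survival_factor)
    truth$growth[detr] <- config$detrimental_growth
    truth$class[ess] <- "essential"
    truth
  })
}

#' Simulate the founding insertion library
#'
#' Samples `n_insertions` distinct insertion sites — uniformly over
#' genome positions, or over the TA dinucleotides of a generated genome
#' sequence when `ta_restricted` — excluding the internal windows of
#' essential genes (insertions in the extremities of essential genes
#' are tolerated and are allowed). Each clone receives a log-normal
#' founding abundance.
#'
#' @param annotation Annotation data.frame.
#' @param truth Output of [simulate_truth()] (or `NULL`: no essentials).
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data.frame `contig`, `position`, `gene_id` (`NA` for
#'   intergenic sites), `abundance`, sorted by position. When
#'   `ta_restricted`, the genome sequence is attached as attribute
#'   `"genome"` (a `Biostrings::DNAString`).
#' @export
simulate_library <- function(annotation, truth = NULL,
                             config = sim_config(), seed = NULL) {
  annotation <- validate_annotation(annotation)
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    L <- as.integer(config$genome_length)
    genome <- NULL
    if (config$ta_restricted) {
      p_gc <- config$gc_content / 2
      p_at <- (1 - config$gc_content) / 2
      genome <- Biostrings::DNAString(paste(
        sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c(p_at, p_gc, p_gc, p_at)),
        collapse = ""))
      candidates <- IRanges::start(
        Biostrings::matchPattern("TA", genome))
    } else {
      candidates <- seq_len(L)
    }
    if (!is.null(truth)) {
      ess <- annotation[annotation$gene_id %in%
                          truth$gene_id[truth$class == "essential"], ,
                        drop = FALSE]
      if (nrow(ess) > 0L) {
        win <- internal_window(ess, config$window_lower,
                               config$window_upper)
        blocked <- unlist(mapply(seq.int, win$win_start[!win$empty],
                                 win$win_end[!win$empty],
                                 SIMPLIFY = FALSE))
        candidates <- setdiff(candidates, blocked)
      }
    }
    if (config$n_insertions > length(candidates)) {
      fail("n_insertions (%d) exceeds the %d available insertion sites",
           as.integer(config$n_insertions), length(candidates))
    }
    pos <- sort(sample(candidates, config$n_insertions))
    gene_of <- rep(NA_character_, length(pos))
    if (nrow(annotation) > 0L) {
      gr_gene <- GenomicRanges::GRanges(
        annotation$contig, IRanges::IRanges(annotation$start,
                                            annotation$end))
      gr_pos <- GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(pos, width = 1L))
      ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_pos, gr_gene))
      gene_of[S4Vectors::queryHits(ov)] <-
        annotation$gene_id[S4Vectors::subjectHits(ov)]
    }
    lib <- data.frame(contig = "chr1", position = pos, gene_id = gene_of,
                      abundance = rlnorm(length(pos), 0,
                                         config$abundance_sdlog),
                      stringsAsFactors = FALSE)
    attr(lib, "genome") <- genome
    lib
  })
}

#' Simulate the arrest-and-recovery experiment
#'
#' The founding library is split in two. The treated pool passes through
#' the arrest bottleneck — clone cell counts are drawn multinomially
#' from the founding abundances at `bottleneck_cells` total, then
#' thinned binomially with each clone's survival probability — and then
#' regrows at `growth x generations_control` generations per hour for
#' `t - 1` hours at harvest time `t` (the one-generation lag). The
#' control pool regrows uniformly for `t` hours. Each harvested sample
#' is sequenced by drawing `depth` reads multinomially from clone
#' proportions (optionally gamma over-dispersed).
#'
#' @param library Output of [simulate_library()].
#' @param truth Output of [simulate_truth()]. Intergenic sites and sites
#'   in gene extremities not covered by the truth table take the
#'   baseline (`s0`, growth 1).
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `counts` (long-format, attribute `"samples"`),
#'   `sheet` (sample sheet) and `bottleneck` (per-clone `cells` and
#'   `survivors` per replicate, for diagnostics).
#' @export
simulate_experiment <- function(library, truth, config = sim_config(),
                                seed = NULL) {
  seed <- seed %||% config$seed
  with_local_seed(seed, {
    idx <- match(library$gene_id, truth$gene_id)
    s <- ifelse(is.na(idx), config$s0, truth$survival[idx])
    # essential-gene extremity insertions behave like wild type
    s[!is.na(idx) & truth$class[idx] == "essential"] <- config$s0
    g <- ifelse(is.na(idx), 1, truth$growth[idx])
    g[!is.na(idx) & truth$class[idx] == "essential"] <- 1
    n <- nrow(library)
    gen_h <- config$generations_control

    sheet <- data.frame(sample_id = character(), condition = character(),
                        time_h = numeric(), replicate = integer(),
                        stringsAsFactors = FALSE)
    counts_list <- list()
    bottleneck <- list()

    draw_reads <- function(w) {
      if (config$depth == 0 || sum(w) <= 0) return(integer(n))
      if (config$dispersion > 0) {
        shp <- 1 / config$dispersion
        w <- w * rgamma(n, shape = shp, rate = shp)
        if (sum(w) <= 0) return(integer(n))
      }
      as.vector(rmultinom(1, config$depth, w))
    }
    add_sample <- function(id, condition, time_h, rep_, reads) {
      sheet[nrow(sheet) + 1L, ] <<- list(id, condition, time_h,
                                         as.integer(rep_))
      keep <- which(reads > 0)
      counts_list[[id]] <<- data.frame(
        sample_id = rep(id, length(keep)), contig = library$contig[keep],
        position = library$position[keep],
        count = as.numeric(reads[keep]), stringsAsFactors = FALSE)
    }

    for (rep_ in seq_len(config$n_replicates)) {
      tag <- if (config$n_replicates > 1) sprintf("_r%d", rep_) else ""
      cells <- as.vector(rmultinom(1, config$bottleneck_cells,
                                   library$abundance))
      survivors <- rbinom(n, cells, s)
      bottleneck[[rep_]] <- data.frame(position = library$position,
                                       replicate = rep_, cells = cells,
                                       survivors = survivors)
      for (tm in config$control_times) {
        w <- library$abundance * 2^(gen_h * tm)
        add_sample(sprintf("ctl_%gh%s", tm, tag), "control", tm, rep_,
                   draw_reads(w))
      }
      for (tm in config$treated_times) {
        w <- survivors * 2^(g * gen_h * (tm - 1))
        add_sample(sprintf("trt_%gh%s", tm, tag), "treated", tm, rep_,
                   draw_reads(w))
      }
    }
    counts <- do.call(rbind, c(counts_list, list(make.row.names = FALSE)))
    attr(counts, "samples") <- sheet$sample_id
    list(counts = counts, sheet = validate_sample_sheet(sheet),
         bottleneck = do.call(rbind, bottleneck))
  })
}

#' One-call synthetic screen
#'
#' Runs [simulate_annotation()], [simulate_truth()],
#' [simulate_library()] and [simulate_experiment()] with stage seeds
#' derived from `config$seed` (stages are individually reproducible).
#'
#' @param config A [sim_config()].
#' @return List `annotation`, `truth`, `library`, `counts`, `sheet`,
#'   `bottleneck`, `config`.
#' @export
simulate_tnseq <- function(config = sim_config()) {
  base <- config$seed
  stage_seed <- function(k) if (is.null(base)) NULL else
    (base + 1000L * k) %% 2147483647L
  annotation <- simulate_annotation(config, seed = stage_seed(1L))
  truth <- simulate_truth(annotation, config, seed = stage_seed(2L))
  library <- simulate_library(annotation, truth, config,
                              seed = stage_seed(3L))
  expt <- simulate_experiment(library, truth, config,
                              seed = stage_seed(4L))
  c(list(annotation = annotation, truth = truth, library = library),
    expt, list(config = config))
}

#' Confusion summary of a screen against the planted truth
#'
#' A true positive is a planted gene called a hit *with the planted
#' direction*: detrimental genes (mutants survive better) must be
#' `enriched_hit`, protective genes `depleted_hit`; a planted gene
#' called with the wrong sign is a sign error, not a true positive.
#' Specificity is computed over the planted-neutral genes; essential
#' genes (no internal insertions by construction) are reported
#' separately.
#'
#' @param results Results data.frame of [run_screen()] (or the
#'   `tn_screen` object).
#' @param truth Truth table of [simulate_truth()]. The gene universes
#'   must match exactly.
#' @return List: `sensitivity`, `specificity`, `sign_accuracy` (`NA`
#'   when no planted gene was called), and the underlying counts.
#' @export
evaluate_recovery <- function(results, truth) {
  if (inherits(results, "tn_screen")) results <- results$results
  assert_columns(results, c("gene_id", "verdict"), "results")
  assert_columns(truth, c("gene_id", "class"), "truth")
  if (!setequal(results$gene_id, truth$gene_id) ||
      nrow(results) != nrow(truth)) {
    fail("results and truth cover different gene universes")
  }
  cls <- truth$class[match(results$gene_id, truth$gene_id)]
  verdict <- results$verdict
  hit <- verdict %in% c("depleted_hit", "enriched_hit")
  planted <- cls %in% c("protective", "detrimental")
  correct <- (cls == "detrimental" & verdict == "enriched_hit") |
    (cls == "protective" & verdict == "depleted_hit")
  n_planted <- sum(planted)
  n_neutral <- sum(cls == "neutral")
  planted_hits <- sum(planted & hit)
  list(
    sensitivity = if (n_planted > 0) sum(correct) / n_planted else NA_real_,
    specificity = if (n_neutral > 0) {
      sum(cls == "neutral" & !hit) / n_neutral
    } else NA_real_,
    sign_accuracy = if (planted_hits > 0) {
      sum(correct) / planted_hits
    } else NA_real_,
    n_planted = n_planted,
    n_neutral = n_neutral,
    n_essential = sum(cls == "essential"),
    n_hits = sum(hit),
    false_positives = sum(!planted & hit)
  )
}
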