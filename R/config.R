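#' Screen pipeline configuration
#'
#' Collects every tunable threshold of the screen into one validated list.
#' The defaults encode the canonical analysis of an HPUra
#' replication-arrest screen: positions with fewer than 3 reads are
#' discarded, genes are scored over their 5--95% internal sequence, and a
#' candidate must (i) be longer than 200 bp, (ii) have more than 5 distinct
#' insertion sites in the control library of the final comparison,
#' (iii) have |log2 fold change| > 1 at the final time point, and (iv) show
#' an amplified change in read frequency over time.
#'
#' @param min_reads_per_position Integer; positions with fewer reads than
#'   this in a sample are discarded from that sample (strict `<`). Default 3.
#' @param window_lower,window_upper Fractions in `[0, 1]` delimiting the
#'   internal portion of each gene over which insertions are counted.
#'   Defaults 0.05 and 0.95.
#' @param min_gene_length Minimum gene length in bp; the length criterion is
#'   strict (`length > min_gene_length`). Default 200.
#' @param min_control_sites Minimum number of distinct insertion sites in
#'   the control sample of the final comparison; strict (`sites >
#'   min_control_sites`). Default 5.
#' @param fc_threshold log2 units; the fold-change criterion is
#'   `|log2 FC| > fc_threshold` at the final time point. Default 1.
#' @param pairing_offset_h Hours by which the control harvest precedes the
#'   treated harvest in each comparison (the arrested pool is one division
#'   generation behind). Default 1.
#' @param final_time_h Treated-sample recovery time (hours) of the final
#'   comparison used for criteria (ii) and (iii). Default 4.
#' @param amplified_mode How criterion (iv), the amplified change over
#'   time, is checked (all modes additionally require every defined fold
#'   change to share the sign of the final one): `"endpoint"` (default)
#'   requires `|log2 FC|` at the final time to be at least that of the
#'   earliest defined time point; `"monotone"` requires `|log2 FC|`
#'   non-decreasing at every step; `"strict"` strictly increasing. The
#'   per-step modes are stronger but reject genes whose per-hour signal
#'   growth is below the sampling noise of one time point.
#' @param pseudocount Added to both frequencies before the log ratio. The
#'   classical analysis uses none; default 0 keeps the +/-Inf sentinels for
#'   one-sided zeros.
#' @param frequency_based Logical; if `TRUE` (default) fold changes are
#'   ratios of genome-wide read *frequencies*, making them sequencing-depth
#'   invariant. If `FALSE`, raw normalized read sums are compared; after
#'   quantile normalization the two differ only by the equalized totals.
#'
#' @return A named list of class `"tn_config"`.
#' @examples
#' cfg <- pipeline_config(fc_threshold = 2)
#' cfg$fc_threshold
#' @export
pipeline_config <- function(min_reads_per_position = 3,
                            window_lower = 0.05,
                            window_upper = 0.95,
                            min_gene_length = 200,
                            min_control_sites = 5,
                            fc_threshold = 1,
                            pairing_offset_h = 1,
                            final_time_h = 4,
                            amplified_mode = c("endpoint", "monotone",
                                               "strict"),
                            pseudocount = 0,
                            frequency_based = TRUE) {
  amplified_mode <- match.arg(amplified_mode)
  cfg <- list(
    min_reads_per_position = min_reads_per_position,
    window_lower = window_lower,
    window_upper = window_upper,
    min_gene_length = min_gene_length,
    min_control_sites = min_control_sites,
    fc_threshold = fc_threshold,
    pairing_offset_h = pairing_offset_h,
    final_time_h = final_time_h,
    amplified_mode = amplified_mode,
    pseudocount = pseudocount,
    frequency_based = isTRUE(frequency_based)
  )
  validate_pipeline_config(cfg)
  class(cfg) <- c("tn_config", "list")
  cfg
}

validate_pipeline_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  if (!num1(cfg$window_lower) || !num1(cfg$window_upper) ||
      cfg$window_lower < 0 || cfg$window_upper > 1 ||
      cfg$window_lower >= cfg$window_upper) {
    fail("window fractions must satisfy 0 <= lower < upper <= 1")
  }
  for (f in c("min_reads_per_position", "min_gene_length",
              "min_control_sites", "fc_threshold", "pairing_offset_h",
              "final_time_h", "pseudocount")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0) {
      fail("config field '%s' must be a non-negative number", f)
    }
  }
  invisible(cfg)
}

# Merge a named list (e.g. parsed YAML) over the defaults, rejecting
# unknown fields.
config_from_list <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    fail("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, x)
}
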