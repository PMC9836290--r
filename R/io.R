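#' Read a gene annotation
#'
#' Reads gene models from GFF3 (records of type `gene`) or from a minimal
#' five-column TSV with header `gene_id contig start end strand`.
#' Coordinates are 1-based inclusive throughout the package (the GFF3
#' convention); `length = end - start + 1`.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` and the derived `length`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tcontig\tstart\tend\tstrand",
#'              "geneA\tchr1\t1\t1000\t+"), tsv)
#' read_annotation(tsv)
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  ann <- if (format == "gff3") read_annotation_gff3(path) else
    read_annotation_tsv(path)
  validate_annotation(ann)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    gr <- gr[as.character(meta$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) {
    return(empty_annotation())
  }
  id <- NULL
  for (field in c("ID", "Name", "locus_tag", "gene_id")) {
    if (field %in% names(meta) && !all(is.na(meta[[field]]))) {
      id <- as.character(meta[[field]])
      break
    }
  }
  if (is.null(id)) fail("GFF3 gene records carry no ID/Name/locus_tag attribute")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(
    gene_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

read_annotation_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = TRUE)
  if (nrow(df) == 0L && ncol(df) <= 1L) return(empty_annotation())
  assert_columns(df, c("gene_id", "contig", "start", "end", "strand"),
                 sprintf("annotation TSV '%s'", path))
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end) | !is_whole(start) | !is_whole(end))
  if (length(bad) > 0L) {
    # +1: header occupies line 1 of the file
    fail("malformed annotation row at line %d of %s", bad[1] + 1L, path)
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L) {
    fail("malformed annotation row at line %d of %s (strand must be + or -)",
         bad_strand[1] + 1L, path)
  }
  data.frame(
    gene_id = df$gene_id,
    contig = df$contig,
    start = as.integer(start),
    end = as.integer(end),
    strand = df$strand,
    stringsAsFactors = FALSE
  )
}

empty_annotation <- function() {
  data.frame(gene_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Validate a gene annotation data.frame
#'
#' Enforces the gene-model invariants: `start >= 1`, `end >= start`,
#' strand in `{+, -}`, unique `gene_id`. Adds/refreshes the `length`
#' column (`end - start + 1`).
#'
#' @param ann A data.frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @return The validated annotation with a `length` column.
#' @export
validate_annotation <- function(ann) {
  assert_columns(ann, c("gene_id", "contig", "start", "end", "strand"),
                 "annotation")
  if (nrow(ann) == 0L) return(empty_annotation())
  if (any(ann$start < 1)) {
    fail("gene '%s': start must be >= 1", ann$gene_id[which(ann$start < 1)[1]])
  }
  bad <- which(ann$end < ann$start)
  if (length(bad) > 0L) {
    fail("gene '%s': end (%d) < start (%d)", ann$gene_id[bad[1]],
         ann$end[bad[1]], ann$start[bad[1]])
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0L) {
    fail("duplicate gene_id in annotation: %s",
         paste(unique(dup), collapse = ", "))
  }
  if (any(!ann$strand %in% c("+", "-"))) fail("strand must be '+' or '-'")
  ann$length <- ann$end - ann$start + 1L
  rownames(ann) <- NULL
  ann
}

#' Write an annotation as minimal TSV
#'
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ann <- validate_annotation(ann)
  write.table(ann[, c("gene_id", "contig", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' @inheritParams write_annotation
#' @export
write_annotation_gff3 <- function(ann, path) {
  ann <- validate_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand,
    type = rep("gene", nrow(ann)),
    ID = ann$gene_id,
    Name = ann$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a per-position insertion count table
#'
#' The table is TSV with header `contig position <sample_1> <sample_2> ...`
#' and one row per genomic position carrying reads in at least one sample.
#' Counts must be non-negative integers; zero cells denote "no insertion
#' reads in that sample" and are dropped from the returned sparse
#' representation.
#'
#' @param path Path to the TSV file.
#' @return A long-format data.frame (`sample_id`, `contig`, `position`,
#'   `count`) holding only non-zero cells, with attribute `"samples"`
#'   giving the full ordered sample list (so samples with no retained
#'   positions are not lost).
#' @export
read_insertion_table <- function(path) {
  if (!file.exists(path)) fail("count table not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  assert_columns(df, c("contig", "position"), sprintf("count table '%s'", path))
  samples <- setdiff(names(df), c("contig", "position"))
  if (nrow(df) > 0L) {
    key <- paste(df$contig, df$position)
    if (anyDuplicated(key)) {
      fail("duplicate (contig, position) row in %s: %s", path,
           key[duplicated(key)][1])
    }
    for (s in samples) {
      v <- df[[s]]
      if (!is.numeric(v) || any(is.na(v))) {
        fail("sample '%s' in %s has non-numeric counts", s, path)
      }
      if (any(v < 0)) fail("sample '%s' in %s has negative counts", s, path)
      if (any(!is_whole(v))) {
        fail("sample '%s' in %s has non-integer counts", s, path)
      }
    }
  }
  long_list <- lapply(samples, function(s) {
    keep <- which(df[[s]] > 0)
    data.frame(sample_id = rep(s, length(keep)),
               contig = df$contig[keep],
               position = as.integer(df$position[keep]),
               count = as.numeric(df[[s]][keep]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(long_list) > 0L) {
    do.call(rbind, c(long_list, list(make.row.names = FALSE)))
  }
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), contig = character(),
                      position = integer(), count = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "samples") <- samples
  out
}

#' Write a per-position insertion count table
#'
#' Inverse of [read_insertion_table()]: pivots the sparse long format to
#' the wide on-disk TSV, filling zeros for absent cells. Counts must be
#' whole numbers (the wide table is the pre-normalization interchange
#' format; normalized real-valued tracks are exported per sample with
#' [write_wiggle()]).
#'
#' @param counts Long-format counts (`sample_id`, `contig`, `position`,
#'   `count`).
#' @param path Output path.
#' @param samples Optional full sample list/order; defaults to the
#'   `"samples"` attribute or the samples present.
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(counts, path, samples = NULL) {
  assert_columns(counts, c("sample_id", "contig", "position", "count"),
                 "counts")
  samples <- samples %||% attr(counts, "samples") %||%
    unique(counts$sample_id)
  if (any(!is_whole(counts$count))) {
    fail("count table writer requires integer counts")
  }
  key <- unique(data.frame(contig = counts$contig,
                           position = counts$position,
                           stringsAsFactors = FALSE))
  key <- key[order(key$contig, key$position), , drop = FALSE]
  wide <- key
  row_idx <- match(paste(counts$contig, counts$position),
                   paste(key$contig, key$position))
  for (s in samples) {
    col <- numeric(nrow(key))
    sel <- counts$sample_id == s
    col[row_idx[sel]] <- counts$count[sel]
    wide[[s]] <- as.integer(round(col))
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with header `sample_id condition time_h replicate`; `condition` is
#' `treated` or `control`, `time_h` the recovery time in hours. The
#' combination (condition, time_h, replicate) must be unique.
#'
#' @param path Path to the TSV file.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) fail("sample sheet not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data.frame
#'
#' @param sheet Data.frame with columns `sample_id`, `condition`,
#'   `time_h`, `replicate`.
#' @return The validated sheet.
#' @export
validate_sample_sheet <- function(sheet) {
  assert_columns(sheet, c("sample_id", "condition", "time_h", "replicate"),
                 "sample sheet")
  if (any(!sheet$condition %in% c("treated", "control"))) {
    fail("condition must be 'treated' or 'control'")
  }
  if (!is.numeric(sheet$time_h) || any(is.na(sheet$time_h)) ||
      any(sheet$time_h < 0)) {
    fail("time_h must be non-negative numbers")
  }
  if (anyDuplicated(sheet$sample_id)) fail("duplicate sample_id in sheet")
  key <- paste(sheet$condition, sheet$time_h, sheet$replicate)
  if (anyDuplicated(key)) {
    fail("duplicate (condition, time_h, replicate) in sheet: %s",
         key[duplicated(key)][1])
  }
  rownames(sheet) <- NULL
  sheet
}

#' Write a sample sheet
#'
#' @param sheet Sample sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the gene-level results table
#'
#' One row per gene with its per-sample site counts, normalized read sums
#' and genome-wide frequencies, the generation-matched log2 fold-change
#' series, the four candidate criteria and the verdict. Undefined fold
#' changes are serialized as the literal `NA` token (never omitted);
#' one-sided zeros keep their `Inf`/`-Inf` sentinels. Values round-trip
#' through [read_gene_results()].
#'
#' @param results The `$results` data.frame of a [run_screen()] object (or
#'   the object itself).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(results, path) {
  if (inherits(results, "tn_screen")) results <- results$results
  if (!is.data.frame(results)) fail("results must be a data.frame")
  if (nrow(results) > 0L && anyNA(results$gene_id)) {
    fail("results rows must all carry a gene_id")
  }
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a gene-level results table written by [write_gene_results()]
#'
#' @param path Path to the TSV file.
#' @return Data.frame with the same columns and types.
#' @export
read_gene_results <- function(path) {
  if (!file.exists(path)) fail("results file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (flag in intersect(c("length_ok", "control_sites_ok", "fc_ok",
                           "amplified_ok"), names(df))) {
    df[[flag]] <- as.logical(df[[flag]])
  }
  df
}

#' Export one sample's counts as a wiggle track
#'
#' Writes a `variableStep` wiggle (1-based coordinates, one chrom block
#' per contig) of a single sample's per-position values — raw integer
#' counts or normalized reals.
#'
#' @param counts Long-format counts.
#' @param sample_id The sample to export.
#' @param path Output path.
#' @param digits Significant digits for real values (default 6).
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(counts, sample_id, path, digits = 6) {
  assert_columns(counts, c("sample_id", "contig", "position", "count"),
                 "counts")
  x <- counts[counts$sample_id == sample_id, , drop = FALSE]
  x <- x[order(x$contig, x$position), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s"', sample_id), con)
  for (ctg in unique(x$contig)) {
    writeLines(sprintf("variableStep chrom=%s", ctg), con)
    sel <- x$contig == ctg
    val_chr <- vapply(x$count[sel], function(v) {
      if (is_whole(v)) sprintf("%d", as.integer(round(v)))
      else as.character(signif(v, digits))
    }, character(1))
    writeLines(paste(x$position[sel], val_chr), con)
  }
  invisible(path)
}
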