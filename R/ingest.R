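## Column layouts of the supported fusion-table dialects. The generic
## dialect is the package's unified schema serialized as TSV; the three
## caller-style dialects are documented minimal layouts, not byte-for-byte
## copies of any historical tool version.
GENERIC_COLUMNS <- c(
  "sample_id", "tool_id",
  "gene5", "chrom5", "strand5", "bp5", "annotated5",
  "gene3", "chrom3", "strand3", "bp3", "annotated3",
  "split_read_count", "spanning_read_count",
  "split_reads", "consensus_sequence",
  "score_pegasus", "score_oncofuse", "annotation"
)

DEFUSE_COLUMNS <- c(
  "gene_name1", "gene_chromosome1", "gene_strand1", "genomic_break_pos1",
  "gene_name2", "gene_chromosome2", "gene_strand2", "genomic_break_pos2",
  "splitr_count", "span_count", "splitr_sequence"
)

CHIMERASCAN_COLUMNS <- c(
  "chrom5p", "break5p", "strand5p", "gene5p",
  "chrom3p", "break3p", "strand3p", "gene3p",
  "split_frags", "spanning_frags", "split_read_seqs"
)

MAPSPLICE_COLUMNS <- c(
  "gene5", "chrom5", "strand5", "bp5",
  "gene3", "chrom3", "strand3", "bp3",
  "split_read_count", "seq"
)

FUSION_DIALECTS <- c("generic", "defuse_like", "chimerascan_like",
                     "mapsplice_like")

read_tsv_dialect <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (!identical(names(df), expected_cols))
    stop("unexpected header in ", path, ": got [",
         paste(names(df), collapse = ","), "], expected [",
         paste(expected_cols, collapse = ","), "]", call. = FALSE)
  df
}

to_int <- function(x, field, path) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & nzchar(x))
  bad <- union(bad, which(!nzchar(x)))
  if (length(bad))
    stop(sprintf("malformed row in %s, line %d: field '%s' = '%s'",
                 path, bad[1] + 1L, field, x[bad[1]]), call. = FALSE)
  out
}

to_num_opt <- function(x, field, path) {
  out <- rep(NA_real_, length(x))
  has <- nzchar(x)
  out[has] <- suppressWarnings(as.numeric(x[has]))
  bad <- which(has & is.na(out))
  if (length(bad))
    stop(sprintf("malformed row in %s, line %d: field '%s' = '%s'",
                 path, bad[1] + 1L, field, x[bad[1]]), call. = FALSE)
  out
}

split_reads_from_field <- function(x) {
  lapply(x, function(s) {
    if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  })
}

opt_chr <- function(x) ifelse(nzchar(x), x, NA_character_)

#' Read fusion calls from a caller output table
#'
#' Parses one of four tab-separated dialects into the unified fusion
#' record table, normalizing all coordinates to 1-based inclusive:
#'
#' * `generic` — the package's own schema (the format [write_fusions()]
#'   emits and the simulator produces); carries sample and tool ids,
#'   annotation status, reads, consensus and scores.
#' * `defuse_like` — 1-based breakpoints and a junction consensus
#'   sequence, no individual split-read sequences.
#' * `chimerascan_like` — interbase (0-based) breakpoint coordinates,
#'   converted to 1-based by adding 1, plus split-read sequences.
#' * `mapsplice_like` — minimal 1-based layout with a junction sequence.
#'
#' @param path path to the TSV file (header required).
#' @param dialect one of `"generic"`, `"defuse_like"`,
#'   `"chimerascan_like"`, `"mapsplice_like"`.
#' @param sample_id sample the file belongs to; required meaning for the
#'   caller dialects (defaults to the file name without extension). The
#'   generic dialect carries its own `sample_id` column and ignores this.
#' @return A validated fusion record `data.frame`.
#' @export
read_fusions <- function(path, dialect = "generic", sample_id = NULL) {
  dialect <- match.arg(dialect, FUSION_DIALECTS)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  rec <- switch(dialect,
    generic = {
      df <- read_tsv_dialect(path, GENERIC_COLUMNS)
      fusion_records(
        sample_id = df$sample_id, tool_id = df$tool_id,
        gene5 = df$gene5, chrom5 = df$chrom5, strand5 = df$strand5,
        bp5 = to_int(df$bp5, "bp5", path),
        gene3 = df$gene3, chrom3 = df$chrom3, strand3 = df$strand3,
        bp3 = to_int(df$bp3, "bp3", path),
        annotated5 = df$annotated5 == "TRUE",
        annotated3 = df$annotated3 == "TRUE",
        split_read_count = to_int(df$split_read_count, "split_read_count",
                                  path),
        spanning_read_count = to_int(df$spanning_read_count,
                                     "spanning_read_count", path),
        split_reads = split_reads_from_field(df$split_reads),
        consensus_sequence = opt_chr(df$consensus_sequence),
        score_pegasus = to_num_opt(df$score_pegasus, "score_pegasus", path),
        score_oncofuse = to_num_opt(df$score_oncofuse, "score_oncofuse",
                                    path),
        annotation = opt_chr(df$annotation)
      )
    },
    defuse_like = {
      df <- read_tsv_dialect(path, DEFUSE_COLUMNS)
      fusion_records(
        sample_id = rep(sample_id, nrow(df)), tool_id = "defuse",
        gene5 = df$gene_name1, chrom5 = df$gene_chromosome1,
        strand5 = df$gene_strand1,
        bp5 = to_int(df$genomic_break_pos1, "genomic_break_pos1", path),
        gene3 = df$gene_name2, chrom3 = df$gene_chromosome2,
        strand3 = df$gene_strand2,
        bp3 = to_int(df$genomic_break_pos2, "genomic_break_pos2", path),
        split_read_count = to_int(df$splitr_count, "splitr_count", path),
        spanning_read_count = to_int(df$span_count, "span_count", path),
        consensus_sequence = opt_chr(df$splitr_sequence)
      )
    },
    chimerascan_like = {
      df <- read_tsv_dialect(path, CHIMERASCAN_COLUMNS)
      fusion_records(
        sample_id = rep(sample_id, nrow(df)), tool_id = "chimerascan",
        gene5 = df$gene5p, chrom5 = df$chrom5p, strand5 = df$strand5p,
        bp5 = to_int(df$break5p, "break5p", path) + 1L,
        gene3 = df$gene3p, chrom3 = df$chrom3p, strand3 = df$strand3p,
        bp3 = to_int(df$break3p, "break3p", path) + 1L,
        split_read_count = to_int(df$split_frags, "split_frags", path),
        spanning_read_count = to_int(df$spanning_frags, "spanning_frags",
                                     path),
        split_reads = split_reads_from_field(df$split_read_seqs)
      )
    },
    mapsplice_like = {
      df <- read_tsv_dialect(path, MAPSPLICE_COLUMNS)
      fusion_records(
        sample_id = rep(sample_id, nrow(df)), tool_id = "mapsplice",
        gene5 = df$gene5, chrom5 = df$chrom5, strand5 = df$strand5,
        bp5 = to_int(df$bp5, "bp5", path),
        gene3 = df$gene3, chrom3 = df$chrom3, strand3 = df$strand3,
        bp3 = to_int(df$bp3, "bp3", path),
        split_read_count = to_int(df$split_read_count, "split_read_count",
                                  path),
        consensus_sequence = opt_chr(df$seq)
      )
    }
  )
  validate_records(rec)
}

fmt_opt_num <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
fmt_opt_chr <- function(x) ifelse(is.na(x), "", x)

write_tsv_plain <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write file: ", path, call. = FALSE)
  invisible(path)
}

#' Write fusion records in a caller dialect
#'
#' The generic dialect round-trips losslessly through [read_fusions()];
#' the `chimerascan_like` writer converts breakpoints back to interbase
#' (0-based) coordinates, making the coordinate normalization a bijection.
#'
#' @param records fusion record `data.frame`.
#' @param path output path.
#' @param dialect output dialect (see [read_fusions()]).
#' @return `path`, invisibly.
#' @export
write_fusions <- function(records, path, dialect = "generic") {
  dialect <- match.arg(dialect, FUSION_DIALECTS)
  validate_records(records)
  reads_field <- vapply(records$split_reads, paste, character(1),
                        collapse = ",")
  df <- switch(dialect,
    generic = data.frame(
      sample_id = records$sample_id, tool_id = records$tool_id,
      gene5 = records$gene5, chrom5 = records$chrom5,
      strand5 = records$strand5, bp5 = records$bp5,
      annotated5 = records$annotated5,
      gene3 = records$gene3, chrom3 = records$chrom3,
      strand3 = records$strand3, bp3 = records$bp3,
      annotated3 = records$annotated3,
      split_read_count = records$split_read_count,
      spanning_read_count = records$spanning_read_count,
      split_reads = reads_field,
      consensus_sequence = fmt_opt_chr(records$consensus_sequence),
      score_pegasus = fmt_opt_num(records$score_pegasus),
      score_oncofuse = fmt_opt_num(records$score_oncofuse),
      annotation = fmt_opt_chr(records$annotation),
      stringsAsFactors = FALSE),
    defuse_like = data.frame(
      gene_name1 = records$gene5, gene_chromosome1 = records$chrom5,
      gene_strand1 = records$strand5, genomic_break_pos1 = records$bp5,
      gene_name2 = records$gene3, gene_chromosome2 = records$chrom3,
      gene_strand2 = records$strand3, genomic_break_pos2 = records$bp3,
      splitr_count = records$split_read_count,
      span_count = records$spanning_read_count,
      splitr_sequence = fmt_opt_chr(records$consensus_sequence),
      stringsAsFactors = FALSE),
    chimerascan_like = data.frame(
      chrom5p = records$chrom5, break5p = records$bp5 - 1L,
      strand5p = records$strand5, gene5p = records$gene5,
      chrom3p = records$chrom3, break3p = records$bp3 - 1L,
      strand3p = records$strand3, gene3p = records$gene3,
      split_frags = records$split_read_count,
      spanning_frags = records$spanning_read_count,
      split_read_seqs = reads_field,
      stringsAsFactors = FALSE),
    mapsplice_like = data.frame(
      gene5 = records$gene5, chrom5 = records$chrom5,
      strand5 = records$strand5, bp5 = records$bp5,
      gene3 = records$gene3, chrom3 = records$chrom3,
      strand3 = records$strand3, bp3 = records$bp3,
      split_read_count = records$split_read_count,
      seq = fmt_opt_chr(records$consensus_sequence),
      stringsAsFactors = FALSE)
  )
  write_tsv_plain(df, path)
}

REPORT_COLUMNS <- c(
  "sample_id", "gene5", "gene3", "chrom5", "bp5", "strand5",
  "chrom3", "bp3", "strand3", "tools", "n_samples_sharing",
  "split_read_count", "spanning_read_count",
  "score_pegasus", "score_oncofuse",
  "structure_label", "reliable", "priority", "removal_stage"
)

report_rows <- function(records, removal_stage) {
  data.frame(
    sample_id = records$sample_id,
    gene5 = records$gene5, gene3 = records$gene3,
    chrom5 = records$chrom5, bp5 = records$bp5, strand5 = records$strand5,
    chrom3 = records$chrom3, bp3 = records$bp3, strand3 = records$strand3,
    tools = records$tools, n_samples_sharing = records$n_samples_sharing,
    split_read_count = records$split_read_count,
    spanning_read_count = records$spanning_read_count,
    score_pegasus = fmt_opt_num(records$score_pegasus),
    score_oncofuse = fmt_opt_num(records$score_oncofuse),
    structure_label = fmt_opt_chr(records$structure_label),
    reliable = records$reliable_structure,
    priority = records$priority,
    removal_stage = removal_stage,
    stringsAsFactors = FALSE
  )
}

#' Construct a per-sample result report
#'
#' @param sample_id sample identifier.
#' @param retained fusion record `data.frame` of records surviving all
#'   filters.
#' @param removed fusion record `data.frame` of removed records.
#' @param removal_stage character vector, one stage name per removed row.
#' @return A `sample_report` object.
#' @export
sample_report <- function(sample_id, retained, removed = empty_fusion_records(),
                          removal_stage = character(0)) {
  stopifnot(length(removal_stage) == nrow(removed))
  structure(list(sample_id = sample_id, retained = retained,
                 removed = removed, removal_stage = removal_stage),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("sample_report for", x$sample_id, "-", nrow(x$retained), "retained,",
      nrow(x$removed), "removed\n")
  invisible(x)
}

#' Write a per-sample result file
#'
#' One TSV with a fixed 19-column layout: retained fusions first (empty
#' `removal_stage`), removed fusions appended with the stage that dropped
#' them. Absent scores and structure labels are written as empty fields,
#' never as 0.
#'
#' @param report a [sample_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  df <- rbind(
    report_rows(report$retained, rep("", nrow(report$retained))),
    report_rows(report$removed, report$removal_stage)
  )
  stopifnot(identical(names(df), REPORT_COLUMNS))
  write_tsv_plain(df, path)
}
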