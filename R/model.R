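#' @keywords internal
"_PACKAGE"

## Structure labels for the four junction hypotheses plus the no-call label.
STRUCTURE_LABELS <- c("PROM_END", "END_PROM", "PROM_PROM", "END_END")
NO_MATCH <- "NO_MATCH"

FLAG_COLUMNS <- c(
  "duplicate_collapsed", "multi_tool", "shared_sample", "shared_with_normal",
  "no_split_reads", "unannotated_partner", "reliable_structure", "priority"
)

OVERLAP_COLUMNS <- c(
  PROM_END = "ov_prom_end", END_PROM = "ov_end_prom",
  PROM_PROM = "ov_prom_prom", END_END = "ov_end_end"
)

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Build a table of fusion records
#'
#' One row per candidate fusion as reported by one caller in one sample.
#' Coordinates are 1-based inclusive genomic positions; `bp5` is the last
#' retained transcribed base of the 5' partner and `bp3` the first retained
#' transcribed base of the 3' partner. Split reads are stored as a list
#' column of character vectors; a record without read sequences may still
#' carry a positive `split_read_count` (consensus-based callers report the
#' count only). Absent consensus sequences and driver scores are `NA`,
#' never 0: an unscored fusion is not a low-scoring one.
#'
#' @param sample_id,tool_id character vectors.
#' @param gene5,chrom5,strand5,bp5 5' partner gene name, chromosome,
#'   strand (`"+"`/`"-"`) and breakpoint.
#' @param gene3,chrom3,strand3,bp3 same for the 3' partner.
#' @param split_read_count,spanning_read_count non-negative integers.
#' @param split_reads list of character vectors of junction-spanning reads.
#' @param consensus_sequence caller consensus across the junction, or `NA`.
#' @param score_pegasus,score_oncofuse driver probabilities in \[0, 1\] or `NA`.
#' @param annotated5,annotated3 logical; whether each partner is an
#'   annotated gene.
#' @param annotation opaque pass-through annotation string (frame, domains,
#'   ...); never interpreted.
#' @return A validated `data.frame` of fusion records.
#' @export
fusion_records <- function(sample_id, tool_id,
                           gene5, chrom5, strand5, bp5,
                           gene3, chrom3, strand3, bp3,
                           split_read_count = 0L,
                           spanning_read_count = 0L,
                           split_reads = NULL,
                           consensus_sequence = NA_character_,
                           score_pegasus = NA_real_,
                           score_oncofuse = NA_real_,
                           annotated5 = TRUE, annotated3 = TRUE,
                           annotation = NA_character_) {
  n <- length(gene5)
  if (is.null(split_reads)) {
    split_reads <- replicate(n, character(0), simplify = FALSE)
  }
  if (!is.list(split_reads)) split_reads <- list(split_reads)
  df <- data.frame(
    sample_id = as.character(sample_id),
    tool_id = as.character(tool_id),
    gene5 = as.character(gene5), chrom5 = as.character(chrom5),
    strand5 = as.character(strand5), bp5 = as.integer(bp5),
    annotated5 = as.logical(rep_len(annotated5, n)),
    gene3 = as.character(gene3), chrom3 = as.character(chrom3),
    strand3 = as.character(strand3), bp3 = as.integer(bp3),
    annotated3 = as.logical(rep_len(annotated3, n)),
    split_read_count = as.integer(rep_len(split_read_count, n)),
    spanning_read_count = as.integer(rep_len(spanning_read_count, n)),
    consensus_sequence = as.character(rep_len(consensus_sequence, n)),
    score_pegasus = as.numeric(rep_len(score_pegasus, n)),
    score_oncofuse = as.numeric(rep_len(score_oncofuse, n)),
    annotation = as.character(rep_len(annotation, n)),
    stringsAsFactors = FALSE
  )
  df$split_reads <- rep_len(split_reads, n)
  df$tools <- df$tool_id
  df$samples <- df$sample_id
  df$n_samples_sharing <- rep(1L, n)
  for (fl in FLAG_COLUMNS) df[[fl]] <- rep(FALSE, n)
  df$structure_label <- rep(NA_character_, n)
  for (ov in OVERLAP_COLUMNS) df[[ov]] <- rep(NA_integer_, n)
  validate_records(df)
}

#' An empty, fully typed fusion record table
#' @return A zero-row fusion record `data.frame`.
#' @export
empty_fusion_records <- function() {
  fusion_records(
    sample_id = character(0), tool_id = character(0),
    gene5 = character(0), chrom5 = character(0),
    strand5 = character(0), bp5 = integer(0),
    gene3 = character(0), chrom3 = character(0),
    strand3 = character(0), bp3 = integer(0)
  )
}

seq_ok <- function(x) {
  !nzchar(gsub(paste(SEQ_ALPHABET, collapse = "|"), "", x))
}

#' Validate fusion record invariants
#'
#' Checks every type invariant of the record table: strands in `{+,-}`,
#' 1-based breakpoints, non-empty gene names, non-negative read counts,
#' `split_read_count == 0` implying an empty read list, ACGTN alphabet for
#' reads and consensus, and driver scores inside \[0, 1\]. Returns the
#' table unchanged; any violation raises an error naming the field and row.
#'
#' @param records fusion record `data.frame`.
#' @return `records`, invisibly unchanged.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  fail <- function(field, rows) {
    stop(sprintf("invalid fusion record: field '%s' (row %s)",
                 field, paste(utils::head(rows, 5), collapse = ",")),
         call. = FALSE)
  }
  chk <- function(ok, field) if (any(!ok)) fail(field, which(!ok))
  chk(nzchar(records$gene5) & !is.na(records$gene5), "gene5")
  chk(nzchar(records$gene3) & !is.na(records$gene3), "gene3")
  chk(records$strand5 %in% c("+", "-"), "strand5")
  chk(records$strand3 %in% c("+", "-"), "strand3")
  chk(!is.na(records$bp5) & records$bp5 >= 1L, "bp5")
  chk(!is.na(records$bp3) & records$bp3 >= 1L, "bp3")
  chk(!is.na(records$split_read_count) & records$split_read_count >= 0L,
      "split_read_count")
  chk(!is.na(records$spanning_read_count) & records$spanning_read_count >= 0L,
      "spanning_read_count")
  n_reads <- vapply(records$split_reads, length, integer(1))
  chk(!(records$split_read_count == 0L & n_reads > 0L), "split_reads")
  chk(vapply(records$split_reads, function(r) all(seq_ok(r)), logical(1)),
      "split_reads")
  cons <- records$consensus_sequence
  chk(is.na(cons) | seq_ok(cons), "consensus_sequence")
  score_ok <- function(s) is.na(s) | (s >= 0 & s <= 1)
  chk(score_ok(records$score_pegasus), "score_pegasus")
  chk(score_ok(records$score_oncofuse), "score_oncofuse")
  records
}

#' Fusion identity key
#'
#' The key on which duplicate collapsing, cross-tool/cross-sample matching,
#' normal subtraction and score attachment all operate: the two partner
#' gene names plus both breakpoints (after 1-based normalization).
#' Reciprocal fusions (A-B vs B-A) are distinct keys, and gene names are
#' compared verbatim. With `with_tool = TRUE` the caller id is included
#' (the duplicate-collapsing key).
#'
#' @param records fusion record `data.frame`.
#' @param with_tool include `tool_id` in the key.
#' @return Character vector of keys, one per row.
#' @export
fusion_key <- function(records, with_tool = FALSE) {
  key <- paste(records$gene5, records$gene3, records$bp5, records$bp3,
               sep = "|")
  if (with_tool) key <- paste(records$tool_id, key, sep = "|")
  key
}
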