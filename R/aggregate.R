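#' Regroup fusion records by sample
#'
#' The cascade is sample-centered: every downstream stage operates on one
#' sample's records and each sample gets its own result file.
#'
#' @param records fusion record `data.frame`.
#' @return Named list of record tables, one per `sample_id`; the union of
#'   the groups is the input and each record falls in exactly one group.
#' @export
group_by_sample <- function(records) {
  if (nrow(records) == 0) return(structure(list(), names = character(0)))
  split(records, records$sample_id)
}

#' Collapse same-tool duplicate calls within one sample
#'
#' A caller can report the same fusion several times with different
#' supporting reads. Records sharing (tool, 5' gene, 3' gene, both
#' breakpoints) are merged into one: split reads are unioned and
#' deduplicated (the count becomes the union size; for consensus-only
#' callers that report no read sequences the maximum reported count is
#' kept instead), the spanning count is the maximum, the consensus is
#' taken from the first record in input order carrying one, and merged
#' records are flagged `duplicate_collapsed`. Idempotent.
#'
#' @param records fusion record `data.frame`, all rows from one sample.
#' @return Collapsed record `data.frame`.
#' @export
collapse_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  if (length(unique(records$sample_id)) > 1L)
    stop("collapse_duplicates expects records from a single sample",
         call. = FALSE)
  key <- fusion_key(records, with_tool = TRUE)
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  out <- lapply(groups, function(idx) {
    row <- records[idx[1], , drop = FALSE]
    if (length(idx) > 1L) {
      grp <- records[idx, , drop = FALSE]
      reads <- unique(unlist(grp$split_reads, use.names = FALSE))
      if (is.null(reads)) reads <- character(0)
      row$split_reads <- list(reads)
      row$split_read_count <- if (length(reads) > 0L) length(reads) else
        max(grp$split_read_count)
      row$spanning_read_count <- max(grp$spanning_read_count)
      cons <- grp$consensus_sequence[!is.na(grp$consensus_sequence)]
      row$consensus_sequence <- if (length(cons)) cons[1] else NA_character_
      row$score_pegasus <- first_present(grp$score_pegasus)
      row$score_oncofuse <- first_present(grp$score_oncofuse)
      for (fl in FLAG_COLUMNS) row[[fl]] <- any(grp[[fl]])
      row$duplicate_collapsed <- TRUE
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  validate_records(out)
}

first_present <- function(x) {
  y <- x[!is.na(x)]
  if (length(y)) y[1] else x[1]
}

#' Label cross-tool and cross-sample recurrence
#'
#' Within a sample, records of the same fusion key reported by more than
#' one caller are flagged `multi_tool` and carry the sorted list of
#' reporting tools. Across samples, records of a key seen in more than
#' one sample are flagged `shared_sample` (the paper's shared vs private
#' fusion distinction) and carry the sorted sample list;
#' `n_samples_sharing` is the number of distinct samples with the key
#' (always `>= 1`). Record counts are never changed.
#'
#' @param groups named list of collapsed record tables as produced by
#'   [group_by_sample()] + [collapse_duplicates()].
#' @return The same-shaped list with flags and recurrence fields filled.
#' @export
label_recurrence <- function(groups) {
  if (length(groups) == 0) return(groups)
  all_rec <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  key_all <- fusion_key(all_rec)
  samples_by_key <- lapply(split(all_rec$sample_id, key_all),
                           function(s) sort(unique(s)))
  lapply(groups, function(rec) {
    if (nrow(rec) == 0) return(rec)
    key <- fusion_key(rec)
    tools_by_key <- lapply(split(rec$tool_id, key),
                           function(t) sort(unique(t)))
    tl <- tools_by_key[key]
    rec$tools <- vapply(tl, paste, character(1), collapse = ",")
    rec$multi_tool <- rec$multi_tool |
      vapply(tl, length, integer(1)) > 1L
    sl <- samples_by_key[key]
    rec$samples <- vapply(sl, paste, character(1), collapse = ",")
    rec$n_samples_sharing <- vapply(sl, length, integer(1))
    rec$shared_sample <- rec$shared_sample | rec$n_samples_sharing > 1L
    rec
  })
}
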