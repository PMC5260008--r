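split_kept_removed <- function(records, keep, flag) {
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) removed[[flag]] <- TRUE
  list(kept = records[keep, , drop = FALSE], removed = removed)
}

#' Remove fusions with unannotated partner genes
#'
#' A fusion is removed when either partner gene name starts with any of
#' the exclusion prefixes (plain case-sensitive prefix test) or when a
#' partner is explicitly marked unannotated. No functional hypothesis or
#' driver probability can be formulated for such partners.
#'
#' @param records fusion record `data.frame`.
#' @param exclude_prefixes character vector of gene-name prefixes; see
#'   [default_exclude_prefixes()].
#' @return `list(kept=, removed=)`; removed records are flagged
#'   `unannotated_partner`.
#' @export
filter_unannotated <- function(records,
                               exclude_prefixes = default_exclude_prefixes()) {
  hit <- function(g) {
    if (length(exclude_prefixes) == 0) return(rep(FALSE, length(g)))
    Reduce(`|`, lapply(exclude_prefixes, function(p) startsWith(g, p)))
  }
  keep <- !(hit(records$gene5) | hit(records$gene3) |
              !records$annotated5 | !records$annotated3)
  split_kept_removed(records, keep, "unannotated_partner")
}

#' Remove tumor fusions shared with healthy samples
#'
#' Fusions whose key (gene pair + both breakpoints) occurs in any of the
#' pooled normal-sample call tables are removed: their presence in
#' non-neoplastic tissue argues against a pathogenic role. Both lists
#' must already be duplicate-collapsed.
#'
#' @param tumor_records,normal_records fusion record tables.
#' @return `list(kept=, removed=)`; removed records are flagged
#'   `shared_with_normal`.
#' @export
filter_normal <- function(tumor_records, normal_records) {
  normal_keys <- if (nrow(normal_records)) fusion_key(normal_records) else
    character(0)
  keep <- !(fusion_key(tumor_records) %in% normal_keys)
  split_kept_removed(tumor_records, keep, "shared_with_normal")
}

#' Remove fusions without split-read support
#'
#' Only fusions supported by at least one split read (a read harbouring
#' the junction within its sequence) are retained: without one the fusion
#' sequence cannot be reconstructed for PCR validation or structure
#' analysis.
#'
#' @param records fusion record `data.frame`.
#' @return `list(kept=, removed=)`; removed records are flagged
#'   `no_split_reads`.
#' @export
filter_split_reads <- function(records) {
  if (any(records$split_read_count < 0))
    stop("negative split_read_count", call. = FALSE)
  split_kept_removed(records, records$split_read_count >= 1L,
                     "no_split_reads")
}
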