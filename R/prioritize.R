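#' Write the driver-score coordinate input file
#'
#' Emits the 5-column tab-separated coordinate file consumed by
#' tissue-aware driver-score classifiers: `chrom5`, `bp5`, `chrom3`,
#' `bp3` and the tumor tissue-of-origin label (`EPI` epithelial, `HEM`
#' hematological, `MES` mesenchymal, `AVG` when unknown). No header.
#'
#' @param records fusion record `data.frame`.
#' @param tissue one of `"EPI"`, `"HEM"`, `"MES"`, `"AVG"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
format_oncofuse_input <- function(records, tissue, path) {
  if (length(tissue) != 1L || !tissue %in% TISSUE_LABELS)
    stop("unknown tissue label: '", tissue, "' (expected ",
         paste(TISSUE_LABELS, collapse = ", "), ")", call. = FALSE)
  df <- data.frame(records$chrom5, records$bp5,
                   records$chrom3, records$bp3,
                   rep(tissue, nrow(records)), stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write file: ", path, call. = FALSE)
  invisible(path)
}

#' Read an external driver-score table
#'
#' TSV with header `gene5, gene3, bp5, bp3, source, score` where `source`
#' is `pegasus` or `oncofuse` and `score` a probability in \[0, 1\].
#'
#' @param path path to the score TSV.
#' @return A `data.frame` of scores.
#' @export
read_scores <- function(path) {
  df <- read_tsv_dialect(path, c("gene5", "gene3", "bp5", "bp3",
                                 "source", "score"))
  data.frame(gene5 = df$gene5, gene3 = df$gene3,
             bp5 = to_int(df$bp5, "bp5", path),
             bp3 = to_int(df$bp3, "bp3", path),
             source = df$source,
             score = to_num_opt(df$score, "score", path),
             stringsAsFactors = FALSE)
}

#' Attach externally computed driver scores
#'
#' Driver probabilities come from external classifiers and are consumed,
#' never computed. Scores are matched on the fusion key (gene pair +
#' breakpoints); records without a matching key keep their scores absent.
#'
#' @param records fusion record `data.frame`.
#' @param score_table `data.frame` as returned by [read_scores()].
#' @return Records with `score_pegasus` / `score_oncofuse` filled where
#'   matched.
#' @export
attach_scores <- function(records, score_table) {
  if (nrow(score_table) == 0) return(records)
  if (!all(score_table$source %in% c("pegasus", "oncofuse")))
    stop("score source must be 'pegasus' or 'oncofuse'", call. = FALSE)
  if (any(is.na(score_table$score) | score_table$score < 0 |
            score_table$score > 1))
    stop("driver scores must lie in [0, 1]", call. = FALSE)
  key <- fusion_key(records)
  skey <- paste(score_table$gene5, score_table$gene3,
                score_table$bp5, score_table$bp3, sep = "|")
  for (src in c("pegasus", "oncofuse")) {
    tab <- score_table[score_table$source == src, , drop = FALSE]
    m <- match(key, skey[score_table$source == src])
    hit <- !is.na(m)
    col <- paste0("score_", src)
    records[[col]][hit] <- tab$score[m[hit]]
  }
  validate_records(records)
}

#' Mark priority fusions
#'
#' The final selection rule: a fusion is *priority* when its structure is
#' biologically reliable and/or either external driver probability is
#' strictly greater than the threshold ("and/or" union semantics; an
#' absent score never exceeds the threshold). Requires structure calls
#' to be present.
#'
#' @param records fusion record `data.frame` with `structure_label` set.
#' @param threshold driver-probability cutoff (default 0.7).
#' @return Records with the `priority` flag set where the rule holds.
#' @export
mark_priority <- function(records, threshold = 0.7) {
  if (nrow(records) && any(is.na(records$structure_label)))
    stop("mark_priority requires a structure call on every record",
         call. = FALSE)
  above <- function(s) !is.na(s) & s > threshold
  records$priority <- records$priority |
    records$reliable_structure |
    above(records$score_pegasus) | above(records$score_oncofuse)
  records
}
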