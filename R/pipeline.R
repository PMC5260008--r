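STAGE_UNANNOTATED <- "unannotated_partner"
STAGE_NORMAL <- "shared_with_normal"
STAGE_NO_SPLIT <- "no_split_reads"

#' Run the full prioritization cascade
#'
#' Executes the stages in fixed order on every sample: regrouping by
#' sample, same-tool duplicate collapsing, cross-tool/cross-sample
#' recurrence labeling, the unannotated-partner filter, subtraction of
#' fusions shared with pooled normal samples, the split-read filter,
#' virtual-reference structure classification, attachment of external
#' driver scores, and priority marking. Writes one result file per sample
#' (and, when a tissue label is configured, a driver-score coordinate
#' file), plus a per-stage count log; one log line per stage per sample
#' goes to standard error. The pipeline proper contains no randomness:
#' identical inputs give byte-identical reports.
#'
#' @param tumor_paths character vector of tumor fusion tables.
#' @param genome_path FASTA of the reference genome.
#' @param normal_paths optional normal-sample fusion tables (pooled).
#' @param score_path optional driver-score TSV (see [read_scores()]).
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param dialect dialect of the tumor/normal tables (recycled across
#'   `tumor_paths`).
#' @return Invisibly, a list with `reports` (named list of
#'   [sample_report()]s), `stage_counts` (data.frame sample_id/stage/
#'   n_in/n_out/n_removed) and `report_paths`.
#' @export
run_pipeline <- function(tumor_paths, genome_path,
                         normal_paths = character(0), score_path = NULL,
                         config = pipeline_config(), outdir,
                         dialect = "generic") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- genome_accessor(genome_path)
  dialect <- rep_len(dialect, length(tumor_paths))

  records <- do.call(rbind, c(
    lapply(seq_along(tumor_paths),
           function(i) read_fusions(tumor_paths[i], dialect[i])),
    list(make.row.names = FALSE)))

  normal <- if (length(normal_paths)) {
    nr <- do.call(rbind, c(
      lapply(normal_paths, function(p) read_fusions(p, "generic")),
      list(make.row.names = FALSE)))
    do.call(rbind, c(lapply(group_by_sample(nr), collapse_duplicates),
                     list(make.row.names = FALSE)))
  } else empty_fusion_records()

  score_table <- if (!is.null(score_path)) read_scores(score_path) else NULL

  groups <- group_by_sample(records)
  groups <- lapply(groups, collapse_duplicates)
  groups <- label_recurrence(groups)

  counts <- list()
  reports <- list()
  report_paths <- character(0)
  for (sid in names(groups)) {
    rec <- groups[[sid]]
    log_stage <- function(stage, n_in, n_out) {
      message(sprintf("sample=%s stage=%s in=%d out=%d removed=%d",
                      sid, stage, n_in, n_out, n_in - n_out))
      counts[[length(counts) + 1L]] <<- data.frame(
        sample_id = sid, stage = stage, n_in = n_in, n_out = n_out,
        n_removed = n_in - n_out, stringsAsFactors = FALSE)
    }
    n0 <- sum(records$sample_id == sid)
    log_stage("collapse", n0, nrow(rec))

    removed <- empty_fusion_records()
    removal_stage <- character(0)
    take <- function(res, stage) {
      removed <<- rbind(removed, res$removed, make.row.names = FALSE)
      removal_stage <<- c(removal_stage, rep(stage, nrow(res$removed)))
      res$kept
    }

    n_in <- nrow(rec)
    rec <- take(filter_unannotated(rec, config$exclude_prefixes),
                STAGE_UNANNOTATED)
    log_stage("filter_unannotated", n_in, nrow(rec))

    n_in <- nrow(rec)
    if (nrow(normal) == 0)
      message(sprintf("sample=%s stage=filter_normal no-op (no normal samples)",
                      sid))
    rec <- take(filter_normal(rec, normal), STAGE_NORMAL)
    log_stage("filter_normal", n_in, nrow(rec))

    n_in <- nrow(rec)
    rec <- take(filter_split_reads(rec), STAGE_NO_SPLIT)
    log_stage("filter_split_reads", n_in, nrow(rec))

    rec <- tryCatch(
      annotate_structure(rec, g, config),
      error = function(e) stop("stage structure failed for sample ", sid,
                               ": ", conditionMessage(e), call. = FALSE))
    log_stage("structure", nrow(rec), nrow(rec))

    if (!is.null(score_table)) rec <- attach_scores(rec, score_table)
    rec <- mark_priority(rec, config$driver_threshold)
    log_stage("priority", nrow(rec), sum(rec$priority))

    if (!is.na(config$tissue))
      format_oncofuse_input(rec, config$tissue,
                            file.path(outdir,
                                      paste0(sid, "_oncofuse_input.tsv")))

    rep_i <- sample_report(sid, rec, removed, removal_stage)
    path_i <- file.path(outdir, paste0(sid, "_report.tsv"))
    write_report(rep_i, path_i)
    reports[[sid]] <- rep_i
    report_paths[sid] <- path_i
  }
  stage_counts <- do.call(rbind, c(counts, list(make.row.names = FALSE)))
  write_tsv_plain(stage_counts, file.path(outdir, "run_log.tsv"))
  invisible(list(reports = reports, stage_counts = stage_counts,
                 report_paths = report_paths))
}
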