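#' Default exclusion prefixes for the unannotated-gene filter
#'
#' Gene-symbol prefixes marking clone-derived, uncharacterized or
#' artifact-prone loci (LOC/AC0/AL0-style accession names, NCRNA, HLA,
#' RNASE, ...). A fusion is dropped when either partner's name starts with
#' any of these.
#'
#' @return Character vector of prefixes.
#' @export
default_exclude_prefixes <- function() {
  c("AC0", "AC1", "AK", "AD0", "AL0", "AL1", "AL5", "AL6", "AP0",
    "NCRNA", "LL22NC", "CTC", "RNASE", "HLA", "BC0", "BC1", "LOC")
}

TISSUE_LABELS <- c("EPI", "HEM", "MES", "AVG")

#' Pipeline configuration
#'
#' All tunables of the prioritization cascade.
#'
#' @param flank_len bases of genomic sequence taken on each side of a
#'   breakpoint when reconstructing virtual junction references; each
#'   reference is `2 * flank_len` long. Default 30.
#' @param min_overlap minimum junction-spanning exact overlap (bp) between
#'   a read/consensus and a virtual reference required to label a fusion
#'   with that structure. Default 15.
#' @param driver_threshold driver-probability cutoff; a fusion scored
#'   strictly above it by either external classifier is priority. Default 0.7.
#' @param exclude_prefixes gene-name prefixes removed by the
#'   unannotated-gene filter.
#' @param tissue tumor tissue-of-origin label for the driver-score
#'   coordinate file, one of `EPI`, `HEM`, `MES`, `AVG`; `NA` when no such
#'   file is requested.
#' @param tie_break_order label preference when two references reach the
#'   same best overlap; defaults to trying the biologically reliable
#'   structures first.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(flank_len = 30L, min_overlap = 15L,
                            driver_threshold = 0.7,
                            exclude_prefixes = default_exclude_prefixes(),
                            tissue = NA_character_,
                            tie_break_order = c("PROM_END", "PROM_PROM",
                                                "END_PROM", "END_END")) {
  flank_len <- as.integer(flank_len)
  min_overlap <- as.integer(min_overlap)
  if (is.na(flank_len) || flank_len < 1L)
    stop("flank_len must be a positive integer", call. = FALSE)
  if (is.na(min_overlap) || min_overlap < 1L || min_overlap > 2L * flank_len)
    stop("min_overlap must satisfy 0 < min_overlap <= 2*flank_len",
         call. = FALSE)
  if (is.na(driver_threshold) || driver_threshold < 0 || driver_threshold > 1)
    stop("driver_threshold must lie in [0, 1]", call. = FALSE)
  if (!is.na(tissue) && !tissue %in% TISSUE_LABELS)
    stop("tissue must be one of ", paste(TISSUE_LABELS, collapse = ", "),
         call. = FALSE)
  if (!setequal(tie_break_order, STRUCTURE_LABELS) ||
      length(tie_break_order) != 4L)
    stop("tie_break_order must be a permutation of the four structure labels",
         call. = FALSE)
  structure(
    list(flank_len = flank_len, min_overlap = min_overlap,
         driver_threshold = driver_threshold,
         exclude_prefixes = as.character(exclude_prefixes),
         tissue = tissue, tie_break_order = tie_break_order),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat("  flank_len:       ", x$flank_len, "bp\n")
  cat("  min_overlap:     ", x$min_overlap, "bp\n")
  cat("  driver_threshold:", x$driver_threshold, "\n")
  cat("  tissue:          ", x$tissue, "\n")
  cat("  exclude_prefixes:", paste(x$exclude_prefixes, collapse = ","), "\n")
  cat("  tie_break_order: ", paste(x$tie_break_order, collapse = " > "), "\n")
  invisible(x)
}

#' Parse a key=value configuration file
#'
#' Recognized keys: `flank_len`, `min_overlap`, `driver_threshold`,
#' `exclude_prefixes` (comma-separated), `tissue`, `tie_break_order`
#' (comma-separated). Blank lines and lines starting with `#` are ignored.
#' Missing keys take the [pipeline_config()] defaults; an unknown key is an
#' error, as is any out-of-range value.
#'
#' @param path path to the configuration file.
#' @return A [pipeline_config()] object.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key=value): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- function(v) {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) stop("invalid numeric value for config key '", key,
                         "': ", v, call. = FALSE)
      x
    }
    args[[key]] <- switch(
      key,
      flank_len = num(val),
      min_overlap = num(val),
      driver_threshold = num(val),
      exclude_prefixes = trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
      tissue = val,
      tie_break_order = trimws(strsplit(val, ",", fixed = TRUE)[[1]]),
      stop("unknown config key: '", key, "'", call. = FALSE)
    )
  }
  do.call(pipeline_config, args)
}
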