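#' Build the four virtual junction references for a fusion
#'
#' For a fusion with breakpoints `bp5` (last retained transcribed base of
#' the 5' partner) and `bp3` (first retained transcribed base of the 3'
#' partner), four candidate junction sequences of length `2 * flank_len`
#' are reconstructed from breakpoint-flanking genomic sequence, one per
#' hypothesis of which gene portions are retained:
#'
#' * `PROM_END`  — promoter side of the 5' gene joined to the 3'-end side
#'   of the 3' gene (the canonical fusion transcript);
#' * `END_PROM`  — promoter side of the 3' gene joined to the 3'-end side
#'   of the 5' gene;
#' * `PROM_PROM` — promoter sides of both partners (second flank
#'   reverse-complemented so the two promoters face each other);
#' * `END_END`   — 3'-end sides of both partners (first flank
#'   reverse-complemented).
#'
#' With `P(x)` = `flank_len` transcript-orientation bases ending at the
#' breakpoint inclusive, `T(x)` = `flank_len` bases starting immediately
#' after it, and `T3(x)` = `flank_len` bases starting at it inclusive:
#' `PROM_END = P(5') T3(3')`, `END_PROM = P(3') T(5')`,
#' `PROM_PROM = P(5') rc(P(3'))`, `END_END = rc(T(5')) T3(3')`.
#' In every reference the junction falls between positions `flank_len`
#' and `flank_len + 1`.
#'
#' @param g a [genome_accessor()].
#' @param f a single-row fusion record `data.frame`.
#' @param flank_len flank length in bp (each reference is twice this).
#' @return A `virtual_reference_set`: list with `refs` (named character
#'   vector over the four labels), `junction_index` and `flank_len`.
#' @export
build_virtual_references <- function(g, f, flank_len = 30L) {
  stopifnot(is.data.frame(f), nrow(f) == 1L)
  flank_len <- as.integer(flank_len)
  if (is.na(flank_len) || flank_len < 1L)
    stop("flank_len must be >= 1", call. = FALSE)
  p5 <- fetch_flank(g, f$chrom5, f$bp5, "ending_at", flank_len, f$strand5)
  t5 <- fetch_flank(g, f$chrom5, f$bp5, "downstream_of", flank_len, f$strand5)
  p3 <- fetch_flank(g, f$chrom3, f$bp3, "ending_at", flank_len, f$strand3)
  t3 <- fetch_flank(g, f$chrom3, f$bp3, "starting_at", flank_len, f$strand3)
  refs <- c(
    PROM_END  = paste0(p5, t3),
    END_PROM  = paste0(p3, t5),
    PROM_PROM = paste0(p5, revcomp(p3)),
    END_END   = paste0(revcomp(t5), t3)
  )
  structure(list(refs = refs, junction_index = flank_len,
                 flank_len = flank_len),
            class = "virtual_reference_set")
}

#' @export
print.virtual_reference_set <- function(x, ...) {
  cat("virtual_reference_set (flank", x$flank_len, "bp, junction after",
      x$junction_index, ")\n")
  for (k in names(x$refs)) cat(sprintf("  %-9s %s\n", k, x$refs[[k]]))
  invisible(x)
}

## Longest exact ungapped run of matches between qc and refc (character
## vectors) that covers ref positions j and j+1; 0 when no alignment
## offset yields at least one matching base on each side of the junction.
## 'N' never matches anything.
match_one_orientation <- function(qc, refc, j) {
  nq <- length(qc)
  nr <- length(refc)
  if (j < 1L || j + 1L > nr || nq < 2L) return(0L)
  best <- 0L
  eq <- function(a, b) a == b & a != "N" & b != "N"
  for (d in (j + 1L - nq):(j - 1L)) {
    ## ref position p pairs with query index p - d
    left <- 0L
    p <- j
    while (p - d >= 1L && p >= 1L && eq(refc[p], qc[p - d])) {
      left <- left + 1L
      p <- p - 1L
    }
    if (left == 0L) next
    right <- 0L
    p <- j + 1L
    while (p - d <= nq && p <= nr && eq(refc[p], qc[p - d])) {
      right <- right + 1L
      p <- p + 1L
    }
    if (right == 0L) next
    if (left + right > best) best <- left + right
  }
  best
}

#' Junction-spanning overlap between a query and a virtual reference
#'
#' Length of the longest exact (ungapped, mismatch-free) common substring
#' between the reference and either the query or its reverse complement
#' that covers the junction, i.e. includes both reference positions
#' `junction_index` and `junction_index + 1`. Returns 0 when no common
#' substring spans the junction. `N` bases never match.
#'
#' @param q query sequence (a split read or caller consensus).
#' @param ref reference sequence.
#' @param junction_index last position of the first flank within `ref`.
#' @return Integer overlap length.
#' @export
match_query <- function(q, ref, junction_index) {
  if (!nzchar(q)) stop("query must be non-empty", call. = FALSE)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rcc <- strsplit(revcomp(q), "", fixed = TRUE)[[1]]
  max(match_one_orientation(qc, refc, junction_index),
      match_one_orientation(rcc, refc, junction_index))
}

#' Classify a fusion's junction structure
#'
#' Matches the fusion's split reads (or, for consensus-based callers, its
#' consensus sequence) against the four virtual references and assigns
#' the structure whose reference achieves the largest junction-spanning
#' overlap of at least `min_overlap` bases; ties are broken by
#' `tie_break_order`. When no reference reaches `min_overlap` the call is
#' `NO_MATCH`.
#'
#' @param f single-row fusion record with at least one split read or a
#'   consensus sequence.
#' @param refs a [build_virtual_references()] result.
#' @param min_overlap minimum junction-spanning overlap in bp.
#' @param tie_break_order label preference order for ties.
#' @return A `structure_call`: list with `label` and `best_overlap`
#'   (named integer vector over the four references).
#' @export
classify_fusion <- function(f, refs, min_overlap = 15L,
                            tie_break_order = c("PROM_END", "PROM_PROM",
                                                "END_PROM", "END_END")) {
  stopifnot(is.data.frame(f), nrow(f) == 1L,
            inherits(refs, "virtual_reference_set"))
  queries <- f$split_reads[[1]]
  if (length(queries) == 0) {
    if (is.na(f$consensus_sequence))
      stop("no split reads and no consensus sequence for fusion ",
           fusion_key(f), call. = FALSE)
    queries <- f$consensus_sequence
  }
  best <- vapply(STRUCTURE_LABELS, function(k) {
    max(vapply(queries, match_query, integer(1),
               ref = refs$refs[[k]], junction_index = refs$junction_index))
  }, integer(1))
  eligible <- tie_break_order[best[tie_break_order] >= min_overlap]
  label <- if (length(eligible) == 0) NO_MATCH else
    eligible[which.max(best[eligible])]
  structure(list(label = label, best_overlap = best),
            class = "structure_call")
}

#' Is a structure call biologically reliable?
#'
#' Reliable fusions retain the promoter side of the 5' partner together
#' with the 3'-end side of the 3' partner (`PROM_END`), or the promoter
#' sides of both partners (`PROM_PROM`): structures compatible with high
#' transcription of the chimera. `END_PROM`, `END_END` and `NO_MATCH`
#' are not reliable.
#'
#' @param call a `structure_call` or a label string.
#' @return Logical.
#' @export
is_reliable <- function(call) {
  label <- if (inherits(call, "structure_call")) call$label else call
  label %in% c("PROM_END", "PROM_PROM")
}

#' Annotate records with structure calls
#'
#' Runs [build_virtual_references()] + [classify_fusion()] on every
#' record, filling `structure_label`, the four per-reference best-overlap
#' columns and the `reliable_structure` flag.
#'
#' @param records fusion record `data.frame` (all with read or consensus
#'   evidence).
#' @param g a [genome_accessor()].
#' @param config a [pipeline_config()].
#' @return The annotated record table.
#' @export
annotate_structure <- function(records, g, config = pipeline_config()) {
  for (i in seq_len(nrow(records))) {
    refs <- build_virtual_references(g, records[i, , drop = FALSE],
                                     config$flank_len)
    call <- classify_fusion(records[i, , drop = FALSE], refs,
                            config$min_overlap, config$tie_break_order)
    records$structure_label[i] <- call$label
    for (k in STRUCTURE_LABELS)
      records[[OVERLAP_COLUMNS[[k]]]][i] <- call$best_overlap[[k]]
    records$reliable_structure[i] <- records$reliable_structure[i] ||
      is_reliable(call)
  }
  records
}
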