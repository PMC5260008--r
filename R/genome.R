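#' Reverse complement of nucleotide strings
#'
#' @param x character vector over the ACGTN alphabet.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Open an indexed FASTA genome
#'
#' Wraps an indexed FASTA file for random access to breakpoint-flanking
#' sequence. The `.fai` index is created on first use if missing.
#' Chromosome names are matched verbatim against the FASTA (no "chr"
#' aliasing), and any query outside `[1, chromosome length]` is an error
#' rather than a silent truncation.
#'
#' @param fasta_path path to a FASTA file.
#' @return A `genome_accessor` object with elements `fafile` and
#'   `chrom_lengths` (named integer vector).
#' @export
genome_accessor <- function(fasta_path) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  if (!file.exists(paste0(fasta_path, ".fai")))
    Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  idx <- Rsamtools::scanFaIndex(fa)
  lens <- GenomicRanges::width(idx)
  names(lens) <- as.character(GenomicRanges::seqnames(idx))
  structure(list(fafile = fa, chrom_lengths = lens),
            class = "genome_accessor")
}

#' @export
print.genome_accessor <- function(x, ...) {
  cat("genome_accessor:", length(x$chrom_lengths), "sequence(s),",
      sum(x$chrom_lengths), "bp total\n")
  invisible(x)
}

#' Fetch genomic sequence (plus strand, 1-based inclusive)
#'
#' @param g a [genome_accessor()].
#' @param chrom chromosome name (verbatim match).
#' @param start,end 1-based inclusive coordinates.
#' @return Upper-case sequence string.
#' @export
get_sequence <- function(g, chrom, start, end) {
  stopifnot(inherits(g, "genome_accessor"))
  if (!chrom %in% names(g$chrom_lengths))
    stop("chromosome '", chrom, "' not present in the FASTA", call. = FALSE)
  len <- g$chrom_lengths[[chrom]]
  if (start < 1L || end > len || start > end)
    stop(sprintf("interval %s:%d-%d outside [1, %d]", chrom, start, end, len),
         call. = FALSE)
  rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  toupper(as.character(Rsamtools::scanFa(g$fafile, rng)[[1]]))
}

#' Extract a breakpoint flank in transcript orientation
#'
#' Returns exactly `length` bases read in the orientation of transcription
#' on `strand`: genomic order on `+`, the reverse complement of the
#' genomic interval mirrored about `pos` on `-`. The `side` anchors the
#' flank relative to `pos` (in transcript coordinates): `ending_at`
#' includes `pos` as the last returned base, `starting_at` as the first,
#' `upstream_of`/`downstream_of` exclude `pos` and abut it.
#'
#' @param g a [genome_accessor()].
#' @param chrom chromosome name.
#' @param pos 1-based anchor position.
#' @param side one of `"upstream_of"`, `"downstream_of"`, `"ending_at"`,
#'   `"starting_at"`.
#' @param length number of bases, `>= 1`.
#' @param strand `"+"` or `"-"`.
#' @return Sequence string of exactly `length` bases.
#' @export
fetch_flank <- function(g, chrom, pos, side, length, strand) {
  side <- match.arg(side, c("upstream_of", "downstream_of",
                            "ending_at", "starting_at"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("flank length must be >= 1", call. = FALSE)
  pos <- as.integer(pos)
  ## transcript-orientation interval, mapped to genomic coordinates
  iv <- if (strand == "+") {
    switch(side,
           ending_at   = c(pos - length + 1L, pos),
           starting_at = c(pos, pos + length - 1L),
           upstream_of = c(pos - length, pos - 1L),
           downstream_of = c(pos + 1L, pos + length))
  } else {
    switch(side,
           ending_at   = c(pos, pos + length - 1L),
           starting_at = c(pos - length + 1L, pos),
           upstream_of = c(pos + 1L, pos + length),
           downstream_of = c(pos - length, pos - 1L))
  }
  s <- get_sequence(g, chrom, iv[1], iv[2])
  if (strand == "-") revcomp(s) else s
}
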