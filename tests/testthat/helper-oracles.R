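## Independent brute-force oracle for the junction-spanning overlap:
## enumerate every substring of ref that covers positions j and j+1 and
## look it up verbatim in q or revcomp(q). Substrings containing N are
## skipped (N never matches), and an N inside q can never equal an
## A/C/G/T literal, so fixed-string search is exact.
brute_force_overlap <- function(q, ref, j) {
  nr <- nchar(ref)
  rcq <- fusionprior::revcomp(q)
  best <- 0L
  for (s in seq_len(j)) {
    for (e in (j + 1L):nr) {
      sub <- substr(ref, s, e)
      if (grepl("N", sub, fixed = TRUE)) next
      if (e - s + 1L <= best) next
      if (grepl(sub, q, fixed = TRUE) || grepl(sub, rcq, fixed = TRUE))
        best <- e - s + 1L
    }
  }
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Write a named character vector of sequences as an indexed FASTA in a
## fresh temporary directory and open it.
make_toy_genome <- function(seqs) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fa <- file.path(dir, "toy.fa")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, fa)
  genome_accessor(fa)
}

## One-line fusion record builder for filter/aggregation tests.
rec <- function(sample_id = "S1", tool_id = "toolA",
                gene5 = "TP53", gene3 = "ERG",
                bp5 = 100L, bp3 = 200L,
                chrom5 = "chrT1", chrom3 = "chrT1",
                strand5 = "+", strand3 = "+",
                split_read_count = 1L, split_reads = list("ACGT"),
                ...) {
  fusion_records(sample_id = sample_id, tool_id = tool_id,
                 gene5 = gene5, chrom5 = chrom5, strand5 = strand5,
                 bp5 = bp5,
                 gene3 = gene3, chrom3 = chrom3, strand3 = strand3,
                 bp3 = bp3,
                 split_read_count = split_read_count,
                 split_reads = split_reads, ...)
}

## Random record table for property tests: keys drawn from a small pool
## so duplicates and cross-tool/cross-sample matches arise.
random_records <- function(n, n_samples = 3, n_tools = 3, key_pool = 12) {
  genes5 <- sprintf("G5_%02d", seq_len(key_pool))
  genes3 <- sprintf("G3_%02d", seq_len(key_pool))
  k <- sample.int(key_pool, n, replace = TRUE)
  reads <- lapply(seq_len(n), function(i) {
    nr <- sample(0:3, 1)
    if (nr == 0) character(0) else
      vapply(seq_len(nr), function(j) rand_seq(10), character(1))
  })
  fusion_records(
    sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
    tool_id = paste0("tool", sample.int(n_tools, n, replace = TRUE)),
    gene5 = genes5[k], chrom5 = "chrT1", strand5 = "+",
    bp5 = 100L + 10L * k,
    gene3 = genes3[k], chrom3 = "chrT2", strand3 = "-",
    bp3 = 500L + 10L * k,
    split_read_count = vapply(reads, length, integer(1)),
    split_reads = reads,
    spanning_read_count = sample(0:5, n, replace = TRUE)
  )
}

## Predict per-stage removal counts for one sample directly from the
## simulator's ground-truth table, respecting the cascade order
## (unannotated -> normal-shared -> split reads).
predict_stage_removals <- function(truth, sample_id) {
  tr <- truth[truth$sample_id == sample_id, , drop = FALSE]
  d <- tr$unannotated_decoy
  e <- !d & tr$planted_in_normal
  f <- !d & !e & tr$n_split_reads == 0L
  list(unannotated = sum(d), normal = sum(e), no_split = sum(f),
       survivors = sum(!d & !e & !f))
}
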