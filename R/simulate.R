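random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A read carrying a junction-centered core of `core_len` bases copied
## from `ref`, padded to `read_len` with random bases. The first padding
## base on each side is forced to mismatch the aligned reference base, so
## the junction-spanning overlap of the read is exactly `core_len`.
sim_read <- function(ref, junction_index, read_len, core_len) {
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  nr <- length(refc)
  core_len <- min(core_len, read_len, nr)
  left <- min(ceiling(core_len / 2), junction_index)
  right <- core_len - left
  if (right > nr - junction_index) {
    right <- nr - junction_index
    left <- core_len - right
  }
  core <- refc[(junction_index - left + 1L):(junction_index + right)]
  pad <- read_len - core_len
  pad_l <- if (pad > 0) sample.int(pad + 1L, 1L) - 1L else 0L
  pad_r <- pad - pad_l
  mismatch <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  left_pad <- character(0)
  if (pad_l > 0) {
    left_pad <- sample(c("A", "C", "G", "T"), pad_l, replace = TRUE)
    p <- junction_index - left  # ref position aligned with last pad base
    if (p >= 1L) left_pad[pad_l] <- mismatch(refc[p])
  }
  right_pad <- character(0)
  if (pad_r > 0) {
    right_pad <- sample(c("A", "C", "G", "T"), pad_r, replace = TRUE)
    p <- junction_index + right + 1L
    if (p <= nr) right_pad[1L] <- mismatch(refc[p])
  }
  paste(c(left_pad, core, right_pad), collapse = "")
}

#' Simulate a toy genome, fusion call tables and ground truth
#'
#' Deterministic test substrate for the whole cascade. Generates a
#' multi-chromosome toy genome of uniform base composition, plants
#' `n_per_class` fusions of each of the four junction structures (both
#' strands represented, breakpoints uniform away from chromosome ends)
#' and emits, in the generic dialect: a tumor call table across
#' `n_samples` samples, a normal-sample call table containing a chosen
#' fraction of the tumor fusions, an external driver-score table, and a
#' ground-truth TSV. Split reads (for half of the fusions, standing in
#' for a read-reporting caller) and consensus sequences (for the other
#' half, a consensus-reporting caller) are sampled from the same virtual
#' junction reference construction the classifier uses, so class recovery
#' is exact by design for error-free junction-spanning evidence.
#'
#' Reads match their generating reference in a junction-centered core of
#' `junction_margin` bases and are padded to `read_len` with random bases
#' whose first position on each side mismatches the reference; setting
#' `junction_margin` below the classifier's minimum overlap therefore
#' forces a `NO_MATCH` call. Additional knobs plant unannotated-gene
#' decoys (removed by the annotation filter) and fusions with zero split
#' reads (removed by the split-read filter); the three planted categories
#' are disjoint so per-stage removal counts are predictable exactly.
#'
#' The same seed always produces byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed governing every random choice.
#' @param n_per_class fusions per structural class.
#' @param read_len split-read / consensus length in bp.
#' @param flank_len flank length used to build the generating references.
#' @param n_reads_per_fusion split reads per read-backed fusion.
#' @param junction_margin junction-spanning matched core length in bp
#'   (defaults to the full read).
#' @param frac_normal_shared fraction of class fusions also planted in the
#'   normal table.
#' @param frac_decoy fraction (of class fusions) of additional decoy
#'   fusions whose 5' partner name carries an excluded prefix.
#' @param frac_no_split fraction of class fusions emitted with zero split
#'   reads and no consensus.
#' @param n_samples tumor samples (fusions assigned round-robin).
#' @param n_chrom,chrom_len toy genome shape.
#' @param score_prob probability that each score source reports a given
#'   class fusion.
#' @param driver_threshold threshold used for the `expected_priority`
#'   ground-truth column.
#' @return Invisibly, a list with file `paths` and the ground-truth
#'   `truth` data.frame.
#' @export
simulate_fusion_data <- function(outdir, seed = 1L, n_per_class = 5L,
                                 read_len = 30L, flank_len = 30L,
                                 n_reads_per_fusion = 3L,
                                 junction_margin = read_len,
                                 frac_normal_shared = 0.1,
                                 frac_decoy = 0.1,
                                 frac_no_split = 0.1,
                                 n_samples = 2L, n_chrom = 2L,
                                 chrom_len = 10000L,
                                 score_prob = 0.3,
                                 driver_threshold = 0.7) {
  if (read_len < 1L) stop("read_len must be >= 1", call. = FALSE)
  if (flank_len < 1L) stop("flank_len must be >= 1", call. = FALSE)
  for (fr in c(frac_normal_shared, frac_decoy, frac_no_split))
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(as.integer(seed), {
    ## toy genome
    chroms <- paste0("chrT", seq_len(n_chrom))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      random_dna(chrom_len), character(1)))
    names(seqs) <- chroms
    fasta <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(seqs, fasta, width = 80L)
    fai <- paste0(fasta, ".fai")
    if (file.exists(fai)) unlink(fai)
    g <- genome_accessor(fasta)

    n_class <- 4L * n_per_class
    n_decoy <- round(frac_decoy * n_class)
    n_total <- n_class + n_decoy
    classes <- c(rep(STRUCTURE_LABELS, each = n_per_class),
                 if (n_decoy > 0)
                   sample(STRUCTURE_LABELS, n_decoy, replace = TRUE))
    is_decoy <- c(rep(FALSE, n_class), rep(TRUE, n_decoy))

    idx_class <- seq_len(n_class)
    n_normal <- round(frac_normal_shared * n_class)
    n_nosplit <- round(frac_no_split * n_class)
    picked <- sample(idx_class, n_normal + n_nosplit)
    in_normal <- seq_len(n_total) %in% picked[seq_len(n_normal)]
    no_split <- seq_len(n_total) %in%
      picked[setdiff(seq_len(n_normal + n_nosplit), seq_len(n_normal))]

    bp_range <- c(flank_len + 1L, chrom_len - flank_len)
    decoy_prefixes <- default_exclude_prefixes()
    rows <- vector("list", n_total)
    truth <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      gene5 <- if (is_decoy[i])
        paste0(sample(decoy_prefixes, 1L), "X", i) else
        sprintf("GENEA%03d", i)
      gene3 <- sprintf("GENEB%03d", i)
      rec <- fusion_records(
        sample_id = paste0("S", (i - 1L) %% n_samples + 1L),
        tool_id = if (i %% 2L == 1L) "simreads" else "simconsensus",
        gene5 = gene5, chrom5 = sample(chroms, 1L),
        strand5 = sample(c("+", "-"), 1L),
        bp5 = sample(bp_range[1]:bp_range[2], 1L),
        gene3 = gene3, chrom3 = sample(chroms, 1L),
        strand3 = sample(c("+", "-"), 1L),
        bp3 = sample(bp_range[1]:bp_range[2], 1L),
        spanning_read_count = sample(0:20, 1L)
      )
      refs <- build_virtual_references(g, rec, flank_len)
      true_ref <- refs$refs[[classes[i]]]
      if (no_split[i]) {
        rec$split_read_count <- 0L
        rec$split_reads <- list(character(0))
        rec$consensus_sequence <- NA_character_
      } else if (rec$tool_id == "simreads") {
        reads <- vapply(seq_len(n_reads_per_fusion), function(k) {
          r <- sim_read(true_ref, refs$junction_index, read_len,
                        junction_margin)
          if (k %% 2L == 0L) revcomp(r) else r
        }, character(1))
        rec$split_reads <- list(unique(reads))
        rec$split_read_count <- length(unique(reads))
      } else {
        rec$consensus_sequence <- sim_read(true_ref, refs$junction_index,
                                           read_len, junction_margin)
        rec$split_read_count <- n_reads_per_fusion
      }
      sp <- if (!is_decoy[i] && stats::runif(1) < score_prob)
        round(stats::runif(1), 3) else NA_real_
      so <- if (!is_decoy[i] && stats::runif(1) < score_prob)
        round(stats::runif(1), 3) else NA_real_
      rows[[i]] <- rec
      truth[[i]] <- data.frame(
        sample_id = rec$sample_id, gene5 = gene5, gene3 = gene3,
        bp5 = rec$bp5, bp3 = rec$bp3, true_label = classes[i],
        planted_in_normal = in_normal[i], unannotated_decoy = is_decoy[i],
        n_split_reads = rec$split_read_count,
        score_pegasus = sp, score_oncofuse = so,
        expected_priority = classes[i] %in% c("PROM_END", "PROM_PROM") |
          (!is.na(sp) & sp > driver_threshold) |
          (!is.na(so) & so > driver_threshold),
        stringsAsFactors = FALSE
      )
    }
    tumor <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))

    paths <- list(genome = fasta,
                  tumor = file.path(outdir, "tumor.tsv"),
                  normal = file.path(outdir, "normal.tsv"),
                  scores = file.path(outdir, "scores.tsv"),
                  truth = file.path(outdir, "truth.tsv"))
    write_fusions(tumor, paths$tumor, "generic")

    normal <- tumor[in_normal, , drop = FALSE]
    if (nrow(normal)) {
      normal$sample_id <- "NORM1"
      normal$samples <- "NORM1"
    }
    write_fusions(normal, paths$normal, "generic")

    has_sp <- !is.na(truth$score_pegasus)
    has_so <- !is.na(truth$score_oncofuse)
    scores <- rbind(
      data.frame(gene5 = truth$gene5[has_sp], gene3 = truth$gene3[has_sp],
                 bp5 = truth$bp5[has_sp], bp3 = truth$bp3[has_sp],
                 source = "pegasus", score = truth$score_pegasus[has_sp],
                 stringsAsFactors = FALSE),
      data.frame(gene5 = truth$gene5[has_so], gene3 = truth$gene3[has_so],
                 bp5 = truth$bp5[has_so], bp3 = truth$bp3[has_so],
                 source = "oncofuse", score = truth$score_oncofuse[has_so],
                 stringsAsFactors = FALSE)
    )
    write_tsv_plain(scores, paths$scores)
    write_tsv_plain(truth, paths$truth)
    invisible(list(paths = paths, truth = truth))
  })
}
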