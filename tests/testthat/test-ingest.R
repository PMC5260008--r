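test_that("generic dialect write-then-read is the identity on records", {
  r <- fusion_records(
    sample_id = c("S1", "S1", "S2"), tool_id = c("defuse", "chimerascan",
                                                 "mapsplice"),
    gene5 = c("BCAS4", "TMPRSS2", "RAD50"), chrom5 = c("c20", "c21", "c5"),
    strand5 = c("+", "-", "+"), bp5 = c(49L, 4200L, 131L),
    gene3 = c("BCAS3", "ERG", "PDLIM4"), chrom3 = c("c17", "c21", "c5"),
    strand3 = c("-", "-", "+"), bp3 = c(59L, 3900L, 201L),
    split_read_count = c(2L, 1L, 0L), spanning_read_count = c(7L, 0L, 3L),
    split_reads = list(c("ACGTN", "GGTT"), "TTAA", character(0)),
    consensus_sequence = c("ACCAAT", NA, NA),
    score_pegasus = c(0.125, NA, 0.5),
    score_oncofuse = c(NA, 0.93, NA),
    annotation = c("frame=in;domain=kinase", NA, NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fusions(r, path, "generic")
  back <- read_fusions(path, "generic")
  expect_equal(back, r)
})

test_that("interbase coordinates are shifted to 1-based and back bijectively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(CHIMERASCAN_COLS <- c("chrom5p", "break5p", "strand5p", "gene5p",
                                "chrom3p", "break3p", "strand3p", "gene3p",
                                "split_frags", "spanning_frags",
                                "split_read_seqs"), collapse = "\t"),
    "c1\t99\t+\tAAA\tc2\t199\t-\tBBB\t2\t1\tACGT,GGCC"
  ), path)
  r <- read_fusions(path, "chimerascan_like", sample_id = "S9")
  expect_identical(r$bp5, 100L)
  expect_identical(r$bp3, 200L)
  expect_identical(r$sample_id, "S9")
  expect_identical(r$tool_id, "chimerascan")
  expect_identical(r$split_reads[[1]], c("ACGT", "GGCC"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_fusions(r, out, "chimerascan_like")
  df <- utils::read.delim(out)
  expect_identical(df$break5p, 99L)
  expect_identical(df$break3p, 199L)
  expect_equal(read_fusions(out, "chimerascan_like", sample_id = "S9"), r)
})

test_that("consensus-style and minimal dialects parse with 1-based coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  r0 <- rec(consensus_sequence = "AACCGGTT", split_read_count = 3L,
            split_reads = list(character(0)))
  write_fusions(r0, path, "defuse_like")
  r <- read_fusions(path, "defuse_like", sample_id = "S1")
  expect_identical(r$tool_id, "defuse")
  expect_identical(r$consensus_sequence, "AACCGGTT")
  expect_identical(r$bp5, r0$bp5)
  write_fusions(r0, path, "mapsplice_like")
  m <- read_fusions(path, "mapsplice_like", sample_id = "S1")
  expect_identical(m$tool_id, "mapsplice")
  expect_identical(m$consensus_sequence, "AACCGGTT")
})

test_that("header-only files give empty record tables; bad input errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fusions(empty_fusion_records(), path, "generic")
  expect_identical(nrow(read_fusions(path, "generic")), 0L)
  expect_error(read_fusions(path, "martian_like"), "arg")
  writeLines(c(readLines(path)[1], "S1\ttoolA\tG1\tc1\t+\tBAD\tTRUE\tG2\tc1\t+\t2\tTRUE\t1\t0\t\t\t\t\t"),
             path)
  expect_error(read_fusions(path, "generic"), "line 2")
  ## wrong header
  writeLines("a\tb\tc", path)
  expect_error(read_fusions(path, "generic"), "header")
})

test_that("dialect adapters always emit validated records", {
  set.seed(11)
  r <- random_records(40)
  for (d in c("generic", "defuse_like", "chimerascan_like",
              "mapsplice_like")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_fusions(r, path, d)
    expect_no_error(validate_records(read_fusions(path, d,
                                                  sample_id = "S1")))
  }
})

test_that("sample reports list retained then removed rows with stage provenance", {
  kept <- rec(score_oncofuse = NA_real_)
  gone <- rec(gene5 = "LOCX1", bp5 = 7L)
  rep <- sample_report("S1", kept, gone, "unannotated_partner")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  expect_identical(df$removal_stage, c("", "unannotated_partner"))
  ## absent score is an empty field, not "0"
  expect_identical(df$score_oncofuse[1], "")
  expect_error(write_report(rep, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})
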