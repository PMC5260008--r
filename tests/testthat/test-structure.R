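## Toy genome used for the hand-derived reference constructions:
## c1 = AACCGGTTAACC (gene5, + strand, breakpoint 4: last retained base)
## c2 = TTGGCCAATTGG (gene3, + strand, breakpoint 7: first retained base)
## Flanks of length 3 by the stated formulas:
##   P5 = c1[2..4] = ACC, T5 = c1[5..7] = GGT,
##   P3 = c2[5..7] = CCA, T3 = c2[7..9] = AAT.
toy_refs <- function(strand5 = "+", strand3 = "+") {
  g <- make_toy_genome(c(c1 = "AACCGGTTAACC", c2 = "TTGGCCAATTGG"))
  f <- rec(chrom5 = "c1", bp5 = 4L, strand5 = strand5,
           chrom3 = "c2", bp3 = 7L, strand3 = strand3)
  build_virtual_references(g, f, flank_len = 3L)
}

test_that("the four virtual references follow the retention hypotheses", {
  refs <- toy_refs()
  expect_identical(refs$junction_index, 3L)
  expect_identical(unname(nchar(refs$refs)), rep(6L, 4))
  expect_identical(refs$refs[["PROM_END"]], paste0("ACC", "AAT"))
  expect_identical(refs$refs[["END_PROM"]], paste0("CCA", "GGT"))
  expect_identical(refs$refs[["PROM_PROM"]], paste0("ACC", revcomp("CCA")))
  expect_identical(refs$refs[["END_END"]], paste0(revcomp("GGT"), "AAT"))
})

test_that("minus-strand partners contribute reverse-complemented flanks", {
  refs <- toy_refs(strand5 = "-", strand3 = "+")
  ## gene5 on "-": P5 = rc(c1[4..6]) = rc(CGG) = CCG, T5 = rc(c1[1..3]) = GGT
  expect_identical(refs$refs[["PROM_END"]], paste0("CCG", "AAT"))
  expect_identical(refs$refs[["END_PROM"]], paste0("CCA", revcomp("AAC")))
})

test_that("degenerate flank requests are rejected", {
  g <- make_toy_genome(c(c1 = "AACCGGTTAACC", c2 = "TTGGCCAATTGG"))
  f <- rec(chrom5 = "c1", bp5 = 4L, chrom3 = "c2", bp3 = 7L)
  expect_error(build_virtual_references(g, f, flank_len = 0L), "flank_len")
  expect_error(build_virtual_references(g, f, flank_len = 50L), "outside")
})

test_that("references over a random genome are pairwise distinct", {
  set.seed(5)
  g <- make_toy_genome(c(c1 = rand_seq(400), c2 = rand_seq(400)))
  for (i in 1:5) {
    f <- rec(chrom5 = "c1", bp5 = sample(50:350, 1),
             strand5 = sample(c("+", "-"), 1),
             chrom3 = "c2", bp3 = sample(50:350, 1),
             strand3 = sample(c("+", "-"), 1))
    refs <- build_virtual_references(g, f, flank_len = 20L)
    expect_identical(anyDuplicated(refs$refs), 0L)
  }
})

test_that("junction overlap: self-match, non-spanning match, and N handling", {
  refs <- toy_refs()
  ref <- refs$refs[["PROM_END"]]  # ACCAAT, junction after 3
  expect_identical(match_query(ref, ref, 3L), 6L)
  ## matches only the left flank: never spans the junction
  expect_identical(match_query("ACC", ref, 3L), 0L)
  ## spans by one base each side
  expect_identical(match_query("CCAA", "ACCAAT", 3L), 4L)
  ## N never matches, breaking the run at the junction
  expect_identical(match_query("CCNA", "ACCAAT", 3L), 0L)
  expect_identical(match_query("CCAA", "ACNAAT", 3L), 0L)
  expect_error(match_query("", ref, 3L), "non-empty")
})

test_that("a 14-base junction block scores 14, below a 15-bp cutoff", {
  set.seed(8)
  ref <- rand_seq(60)
  block <- substr(ref, 24, 37)  # 14 bases covering the 30|31 junction
  expect_identical(match_query(block, ref, 30L), 14L)
  expect_lt(match_query(block, ref, 30L), 15L)
})

test_that("overlap is symmetric under reverse complement of the query", {
  set.seed(31)
  for (i in 1:50) {
    ref <- rand_seq(40, c("A", "C", "G", "T", "N"))
    q <- rand_seq(25, c("A", "C", "G", "T", "N"))
    expect_identical(match_query(q, ref, 20L),
                     match_query(revcomp(q), ref, 20L))
  }
})

test_that("overlap equals the brute-force substring oracle on random pairs", {
  set.seed(13)
  for (i in 1:150) {
    ref <- rand_seq(40)
    j <- sample(5:35, 1)
    q <- if (i %% 3 == 0) {
      ## embed a junction-spanning chunk so nonzero overlaps occur often
      s <- sample(max(1, j - 12):j, 1)
      e <- sample((j + 1):min(40, j + 12), 1)
      paste0(rand_seq(5), substr(ref, s, e), rand_seq(5))
    } else rand_seq(25)
    expect_identical(match_query(q, ref, j), brute_force_overlap(q, ref, j))
  }
})

test_that("classification recovers the generating reference and honors the cutoff", {
  set.seed(19)
  g <- make_toy_genome(c(c1 = rand_seq(500), c2 = rand_seq(500)))
  for (label in c("PROM_END", "END_PROM", "PROM_PROM", "END_END")) {
    f <- rec(chrom5 = "c1", bp5 = sample(60:440, 1),
             strand5 = sample(c("+", "-"), 1),
             chrom3 = "c2", bp3 = sample(60:440, 1),
             strand3 = sample(c("+", "-"), 1))
    refs <- build_virtual_references(g, f, flank_len = 30L)
    reads <- vapply(1:3, function(k)
      substr(refs$refs[[label]], 10 + k, 39 + k), character(1))
    f$split_reads <- list(reads)
    f$split_read_count <- 3L
    call <- classify_fusion(f, refs, min_overlap = 15L)
    expect_identical(call$label, label)
    expect_gte(call$best_overlap[[label]], 15L)
    ## reverse-complemented evidence gives the identical call
    f_rc <- f
    f_rc$split_reads <- list(revcomp(reads))
    call_rc <- classify_fusion(f_rc, refs, min_overlap = 15L)
    expect_identical(call_rc$label, call$label)
    expect_identical(call_rc$best_overlap, call$best_overlap)
    ## raising min_overlap beyond the best evidence forces NO_MATCH,
    ## never a different label
    strict <- classify_fusion(f, refs,
                              min_overlap = max(call$best_overlap) + 1L)
    expect_identical(strict$label, "NO_MATCH")
    expect_true(all(strict$best_overlap < max(call$best_overlap) + 1L))
  }
})

test_that("short evidence yields NO_MATCH and consensus stands in for reads", {
  set.seed(29)
  g <- make_toy_genome(c(c1 = rand_seq(300), c2 = rand_seq(300)))
  f <- rec(chrom5 = "c1", bp5 = 100L, chrom3 = "c2", bp3 = 150L)
  refs <- build_virtual_references(g, f, flank_len = 30L)
  f$split_reads <- list(substr(refs$refs[["PROM_END"]], 25, 34))  # 10 bp
  f$split_read_count <- 1L
  expect_identical(classify_fusion(f, refs, min_overlap = 15L)$label,
                   "NO_MATCH")
  ## consensus-only record
  f2 <- rec(chrom5 = "c1", bp5 = 100L, chrom3 = "c2", bp3 = 150L,
            split_read_count = 2L, split_reads = list(character(0)),
            consensus_sequence = substr(refs$refs[["END_PROM"]], 11, 50))
  expect_identical(classify_fusion(f2, refs, min_overlap = 15L)$label,
                   "END_PROM")
  f3 <- rec(split_read_count = 2L, split_reads = list(character(0)))
  expect_error(classify_fusion(f3, refs, 15L), "no split reads")
})

test_that("ties are resolved by the configured label preference", {
  ## two references made identical by a palindromic-free hand genome:
  ## craft refs directly
  refs <- structure(list(
    refs = c(PROM_END = "AAAATTTT", END_PROM = "AAAATTTT",
             PROM_PROM = "CCCCGGGG", END_END = "CCCCGGGG"),
    junction_index = 4L, flank_len = 4L), class = "virtual_reference_set")
  f <- rec(split_reads = list("AAAATTTT"), split_read_count = 1L)
  expect_identical(classify_fusion(f, refs, 4L)$label, "PROM_END")
  expect_identical(
    classify_fusion(f, refs, 4L,
                    tie_break_order = c("END_PROM", "END_END", "PROM_PROM",
                                        "PROM_END"))$label,
    "END_PROM")
})

test_that("reliability covers exactly the promoter-retaining structures", {
  expect_true(is_reliable("PROM_END"))
  expect_true(is_reliable("PROM_PROM"))
  expect_false(is_reliable("END_PROM"))
  expect_false(is_reliable("END_END"))
  expect_false(is_reliable("NO_MATCH"))
})
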