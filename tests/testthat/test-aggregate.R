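test_that("grouping by sample partitions the records", {
  set.seed(3)
  r <- random_records(60)
  gr <- group_by_sample(r)
  expect_identical(sum(vapply(gr, nrow, integer(1))), nrow(r))
  for (sid in names(gr)) expect_true(all(gr[[sid]]$sample_id == sid))
  expect_length(group_by_sample(empty_fusion_records()), 0L)
  one <- r[r$sample_id == r$sample_id[1], ]
  expect_length(group_by_sample(one), 1L)
})

test_that("same-tool same-key records merge with unioned reads", {
  r <- rbind(
    rec(split_reads = list(c("AAAA", "CCCC")), split_read_count = 2L,
        spanning_read_count = 5L, consensus_sequence = NA_character_),
    rec(split_reads = list(c("CCCC", "GGGG")), split_read_count = 2L,
        spanning_read_count = 9L, consensus_sequence = "ACGT"),
    make.row.names = FALSE)
  out <- collapse_duplicates(r)
  expect_identical(nrow(out), 1L)
  expect_setequal(out$split_reads[[1]], c("AAAA", "CCCC", "GGGG"))
  expect_identical(out$split_read_count, 3L)
  expect_identical(out$spanning_read_count, 9L)
  expect_identical(out$consensus_sequence, "ACGT")
  expect_true(out$duplicate_collapsed)
})

test_that("distinct breakpoints or tools are never merged; singletons untouched", {
  r <- rbind(rec(bp3 = 200L), rec(bp3 = 201L), make.row.names = FALSE)
  expect_identical(nrow(collapse_duplicates(r)), 2L)
  r2 <- rbind(rec(tool_id = "toolA"), rec(tool_id = "toolB"),
              make.row.names = FALSE)
  expect_identical(nrow(collapse_duplicates(r2)), 2L)
  single <- rec()
  out <- collapse_duplicates(single)
  expect_false(out$duplicate_collapsed)
  expect_equal(out, single)
})

test_that("consensus-only duplicates keep the maximum reported read count", {
  r <- rbind(
    rec(split_read_count = 2L, split_reads = list(character(0)),
        consensus_sequence = "AAAA"),
    rec(split_read_count = 5L, split_reads = list(character(0)),
        consensus_sequence = "CCCC"),
    make.row.names = FALSE)
  out <- collapse_duplicates(r)
  expect_identical(out$split_read_count, 5L)
  expect_identical(out$consensus_sequence, "AAAA")
})

test_that("collapsing is idempotent, shrinking, read-conserving, and matches a brute-force oracle", {
  set.seed(17)
  for (i in 1:10) {
    r <- random_records(sample(5:200, 1))
    r <- r[r$sample_id == "S1", , drop = FALSE]
    if (nrow(r) == 0) next
    once <- collapse_duplicates(r)
    expect_lte(nrow(once), nrow(r))
    expect_equal(collapse_duplicates(once), once)
    expect_setequal(unlist(once$split_reads), unlist(r$split_reads))
    ## oracle: group indices by key and compare membership
    oracle_groups <- split(seq_len(nrow(r)), fusion_key(r, with_tool = TRUE))
    expect_identical(nrow(once), length(oracle_groups))
    expect_setequal(fusion_key(once, with_tool = TRUE),
                    names(oracle_groups))
  }
  expect_error(collapse_duplicates(random_records(50)), "single sample")
})

test_that("recurrence labeling flags multi-tool and shared-sample fusions", {
  r <- rbind(
    rec(sample_id = "S1", tool_id = "toolA"),
    rec(sample_id = "S1", tool_id = "toolB"),
    rec(sample_id = "S2", tool_id = "toolA"),
    rec(sample_id = "S1", tool_id = "toolA", gene5 = "UNIQ", bp5 = 9L),
    make.row.names = FALSE)
  gr <- label_recurrence(lapply(group_by_sample(r), collapse_duplicates))
  s1 <- gr$S1
  shared <- s1[s1$gene5 == "TP53", ]
  expect_true(all(shared$multi_tool))
  expect_identical(unique(shared$tools), "toolA,toolB")
  expect_true(all(shared$shared_sample))
  expect_identical(unique(shared$n_samples_sharing), 2L)
  expect_identical(unique(shared$samples), "S1,S2")
  uniq <- s1[s1$gene5 == "UNIQ", ]
  expect_false(uniq$multi_tool)
  expect_false(uniq$shared_sample)
  expect_identical(uniq$n_samples_sharing, 1L)
  ## never changes record counts
  expect_identical(vapply(gr, nrow, integer(1)),
                   vapply(lapply(group_by_sample(r), collapse_duplicates),
                          nrow, integer(1)))
})
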