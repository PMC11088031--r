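test_that("make_tasks lays out the four starting sequences", {
  s1 <- random_seq(40)
  s2 <- random_seq(40)
  tk <- make_tasks(s1, s2)
  expect_identical(tk$T1$contig, s1)
  expect_identical(tk$T2$contig, reverse_complement(s2))
  expect_identical(tk$T3$contig, s2)
  expect_identical(tk$T4$contig, reverse_complement(s1))
  expect_identical(tk$T1$mate_target, reverse_complement(s2))
  expect_identical(tk$T3$mate_target, reverse_complement(s1))
  expect_null(tk$T2$mate_target)
  expect_true(all(vapply(tk, `[[`, "", "state") == "active"))
  expect_identical(tk$T1$partner, "T2")
  expect_identical(tk$T3$partner, "T4")
  expect_identical(vapply(tk, `[[`, "", "role"),
                   c(T1 = "primary", T2 = "auxiliary",
                     T3 = "primary", T4 = "auxiliary"))
})

test_that("the overlap filter reproduces the decile threshold rule", {
  # O values 0.55, 0.78, 0.71 -> T = 0.7; only the 0.55 entry is removed
  batch <- data.frame(id = c(11L, 12L, 13L), overlap = c(55L, 78L, 71L))
  out <- filter_candidates(batch, anchor_len = 100L)
  expect_identical(out$id, c(12L, 13L))
  expect_equal(attr(out, "threshold"), 0.7)
})

test_that("paired candidates are rescued below the threshold", {
  # id 3 has O = 0.5 < T but its mate (id 4) sits in the partner batch
  batch <- data.frame(id = c(1L, 3L), overlap = c(95L, 50L))
  partner <- data.frame(id = c(4L, 99L))
  out <- filter_candidates(batch, 100L, partner)
  expect_identical(out$id, c(1L, 3L))
  expect_identical(out$is_paired_rescue, c(FALSE, TRUE))
  # partner terminated: same entry now subject to the threshold rule
  out2 <- filter_candidates(batch, 100L, NULL)
  expect_identical(out2$id, 1L)
})

test_that("threshold is exact at decile boundaries", {
  batch <- data.frame(id = 1:3, overlap = c(100L, 70L, 69L))
  out <- filter_candidates(batch, 100L)
  expect_equal(attr(out, "threshold"), 1.0)
  expect_identical(out$id, 1L)
  # all rescued: threshold undefined, everything kept
  allp <- filter_candidates(batch, 100L, data.frame(id = mate_id(1:3)))
  expect_identical(allp$id, 1:3)
  expect_true(is.na(attr(allp, "threshold")))
})

test_that("mate_id follows the interleaved convention", {
  expect_identical(mate_id(c(1L, 2L, 5L, 6L)), c(2L, 1L, 6L, 5L))
})

sim20 <- tiny_sim()

test_that("an indexed window retrieves itself with a perfect placement", {
  reads <- interleave_pairs(sim20$sim$pairs)
  ids <- query_candidates(reads[5], sim20$idx)
  expect_true(5L %in% ids)
  a <- best_alignment(reads[5], index_reads(sim20$idx, 5L))
  expect_equal(a$shift, 0L)
  expect_equal(a$mismatches, 0L)
})

test_that("candidate batches carry admissible placements and exact O values", {
  reads <- interleave_pairs(sim20$sim$pairs)
  w <- reads[1]
  b <- gather_candidates(sim20$idx, w, exclude = c(1L, 2L))
  expect_false(any(b$id %in% c(1L, 2L)))          # self pair excluded
  expect_true(all(b$id %in% attr(b, "retrieved")))
  expect_true(all(b$mismatches <= 5L))
  expect_true(all(b$shift >= 0L))
  # O recomputed independently from the alignments
  expect_equal(b$O, b$overlap / nchar(w))
  # without exclusion the window's own read is a perfect hit
  b2 <- gather_candidates(sim20$idx, w)
  self <- b2[b2$id == 1L, ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$shift, 0L)
  expect_equal(self$mismatches, 0L)
})

test_that("a noiseless pair over a covered region connects both ways", {
  res <- extend_read_pair(sim20$idx, 10, sim20$params)
  expect_identical(res$tasks$T1$state, "mate_found")
  expect_identical(res$tasks$T3$state, "mate_found")
  g1 <- res$tasks$T1$mate_pos - res$tasks$T1$start_len
  g3 <- res$tasks$T3$mate_pos - res$tasks$T3$start_len
  expect_equal(g1, g3)  # identical gap lengths from both directions
  expect_true(all(res$connected))
})

test_that("auxiliary tasks stop when their partner stops", {
  res <- extend_read_pair(sim20$idx, 3, sim20$params)
  if (res$tasks$T1$state %in% c("mate_found", "failed")) {
    expect_identical(res$tasks$T2$state, "stopped")
  }
  if (res$tasks$T3$state %in% c("mate_found", "failed")) {
    expect_identical(res$tasks$T4$state, "stopped")
  }
})

test_that("extension is impossible without spanning reads", {
  # index contains only the pair itself: no reads cover the gap
  s1 <- random_seq(50)
  s2 <- random_seq(50)
  idx <- build_read_index(c(s1, s2), hash_family(8, 16, 1))
  res <- extend_read_pair(idx, 1,
                          extension_params(150, 5, min_length = 110,
                                           max_length = 170))
  expect_identical(res$tasks$T1$state, "failed")
  expect_identical(res$tasks$T3$state, "failed")
  expect_false(any(res$connected))
})

test_that("original read bases are preserved verbatim in every contig", {
  reads <- interleave_pairs(sim20$sim$pairs)
  for (p in c(2, 8, 21)) {
    res <- extend_read_pair(sim20$idx, p, sim20$params)
    r1 <- reads[2 * p - 1]
    r2 <- reads[2 * p]
    expect_identical(substr(res$tasks$T1$contig, 1, nchar(r1)), r1)
    expect_identical(substr(res$tasks$T3$contig, 1, nchar(r2)), r2)
    if (res$tasks$T1$state == "mate_found") {
      n <- nchar(res$tasks$T1$contig)
      expect_identical(substr(res$tasks$T1$contig, n - nchar(r2) + 1, n),
                       reverse_complement(r2))
    }
  }
})

test_that("found mates land inside the allowed length window", {
  p <- sim20$params
  res <- extend_pairs(sim20$idx, p)
  pr <- plrex:::resolve_params(p, read_lengths = c(100, 100))
  found <- !is.na(res$gap_end)
  lens <- nchar(res$sequence[found])
  expect_true(all(lens >= pr$min_length & lens <= pr$max_length))
})

test_that("pairs with reads shorter than k are reported unextendable", {
  idx <- build_read_index(c("ACGTACG", random_seq(50)),
                          hash_family(8, 16, 1))
  res <- extend_read_pair(idx, 1,
                          extension_params(120, 5, min_length = 60,
                                           max_length = 140))
  expect_identical(res$tasks$T1$state, "failed")
  expect_false(any(res$connected))
})
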