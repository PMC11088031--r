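mk_members <- function(seqs, shifts, orient = NULL) {
  data.frame(sequence = seqs, shift = shifts,
             orientation = if (is.null(orient)) rep("forward", length(seqs))
                           else orient,
             stringsAsFactors = FALSE)
}

test_that("an MSA without candidates is the anchor itself", {
  a <- random_seq(30)
  m <- build_msa(a)
  expect_equal(m$ncol, 30L)
  expect_true(all(m$coverage == 1L))
  expect_identical(msa_consensus(m), a)
})

test_that("a candidate identical to the anchor doubles every column", {
  a <- random_seq(25)
  m <- build_msa(a, mk_members(a, 0L))
  expect_equal(m$ncol, 25L)
  expect_true(all(m$coverage == 2L))
  expect_identical(msa_consensus(m), a)
})

test_that("column coverage equals a hand-computed overlay of three reads", {
  a <- strrep("A", 10)
  m <- build_msa(a, mk_members(c("AAAAA", "AAAAAAA", "AAAA"),
                               c(0L, 5L, 8L)))
  # anchor covers 1..10; members cover 1..5, 6..12, 9..12
  expect_equal(m$ncol, 12L)
  expect_equal(m$coverage,
               c(2, 2, 2, 2, 2, 2, 2, 2, 3, 3, 2, 2))
  expect_equal(unname(m$counts["A", ]), m$coverage)
})

test_that("reverse-complement members contribute their oriented bases", {
  m <- build_msa("ACGT", mk_members("ACGT", 0L, "revcomp"))
  # revcomp("ACGT") == "ACGT": palindromic, counts double
  expect_true(all(m$coverage == 2L))
  m2 <- build_msa("AAAA", mk_members("TTTT", 0L, "revcomp"))
  expect_equal(unname(m2$counts["A", ]), rep(2L, 4))
})

test_that("per-column counts always sum to the coverage", {
  set.seed(401)
  for (i in 1:20) {
    a <- random_seq(sample(10:40, 1))
    nmem <- sample(0:6, 1)
    mem <- mk_members(
      vapply(seq_len(nmem), function(j) random_seq(sample(5:30, 1)),
             character(1)),
      sample(0:(nchar(a) - 1L), nmem, replace = TRUE),
      sample(c("forward", "revcomp"), nmem, replace = TRUE))
    m <- build_msa(a, mem)
    expect_equal(unname(colSums(m$counts)), m$coverage)
    expect_equal(m$ncol,
                 max(nchar(a), max(c(0, mem$shift + nchar(mem$sequence)))))
  }
})

test_that("consensus takes the per-column majority with lexicographic ties", {
  counts <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[, 1] <- c(2L, 0L, 2L, 0L)  # A/G tie -> A
  counts[, 2] <- c(0L, 3L, 0L, 1L)  # C
  counts[, 3] <- c(0L, 0L, 0L, 4L)  # T
  expect_identical(plrex:::cpp_consensus_from_counts(counts), "ACT")
})

test_that("consensus equals an independently tabulated argmax", {
  set.seed(402)
  for (i in 1:10) {
    a <- random_seq(20)
    mem <- mk_members(vapply(1:4, function(j) random_seq(15), character(1)),
                      sample(0:10, 4, replace = TRUE))
    m <- build_msa(a, mem)
    # oracle: tally characters column by column
    rows <- c(list(c(strsplit(a, "")[[1]], rep(NA, m$ncol - nchar(a)))),
              lapply(seq_len(4), function(j) {
                s <- strsplit(mem$sequence[j], "")[[1]]
                out <- rep(NA, m$ncol)
                out[mem$shift[j] + seq_along(s)] <- s
                out
              }))
    tab <- sapply(seq_len(m$ncol), function(col) {
      obs <- stats::na.omit(vapply(rows, `[`, "", col))
      counts <- table(factor(obs, levels = c("A", "C", "G", "T")))
      names(counts)[which.max(counts)]  # which.max: first max = smallest base
    })
    expect_identical(msa_consensus(m), paste(tab, collapse = ""))
  }
})

test_that("the 0.3 x coverage refinement removes repeat-like members", {
  # column 1: coverage 10 (anchor + 9 members), consensus A, anchor A,
  # four members carry G (0.4 >= 0.3) -> exactly those four are removed
  a <- strrep("A", 8)
  mem <- mk_members(c(rep(strrep("A", 8), 5),
                      rep(paste0("G", strrep("A", 7)), 4)),
                    rep(0L, 9))
  m <- refine_msa(build_msa(a, mem))
  expect_equal(nrow(m$members), 5L)
  expect_true(all(m$members$sequence == strrep("A", 8)))
})

test_that("refinement keeps members that agree with a divergent anchor", {
  # anchor carries the non-consensus base x: members lacking x are removed
  a <- paste0("G", strrep("A", 7))  # anchor has G at column 1
  mem <- mk_members(c(rep(strrep("A", 8), 6),
                      rep(paste0("G", strrep("A", 7)), 3)),
                    rep(0L, 9))
  # column 1: coverage 10, consensus A (6 A vs 4 G), x = G count 4 >= 3
  m <- refine_msa(build_msa(a, mem))
  expect_equal(nrow(m$members), 3L)
  expect_true(all(substr(m$members$sequence, 1, 1) == "G"))
})

test_that("refinement is vacuous below the threshold", {
  a <- strrep("A", 10)
  mem <- mk_members(c(rep(strrep("A", 10), 8),
                      rep(paste0("C", strrep("A", 9)), 2)),
                    rep(0L, 10))
  # C count 2 of coverage 11 < 0.3 -> nothing removed
  m <- refine_msa(build_msa(a, mem))
  expect_equal(nrow(m$members), 10L)
})

test_that("extension appends the covered consensus beyond the anchor", {
  a <- random_seq(20)
  ext <- random_seq(7)
  tail20 <- paste0(substr(a, 14, 20), ext)  # 7 anchor bases + 7 new
  mem <- mk_members(rep(paste0(substr(a, 7, 20), ext), 3), rep(6L, 3))
  m <- build_msa(a, mem)
  r <- extend_window(m)
  expect_equal(r$status, "extended")
  expect_identical(r$appended, ext)
  expect_identical(r$new_window, paste0(substr(a, 8, 20), ext))
  expect_equal(nchar(r$new_window), nchar(a))
})

test_that("extension fails without columns beyond the anchor", {
  a <- random_seq(15)
  m <- build_msa(a, mk_members(a, 0L))
  expect_equal(extend_window(m)$status, "failed")
})

test_that("extension fails when the first new column is under-covered", {
  a <- random_seq(10)
  mem <- mk_members(rep(paste0(substr(a, 6, 10), "ACGTA"), 2), rep(5L, 2))
  m <- build_msa(a, mem)
  expect_equal(extend_window(m, min_coverage = 3L)$status, "failed")
  expect_equal(extend_window(m, min_coverage = 2L)$status, "extended")
})

test_that("extension never appends more than stepsize bases", {
  set.seed(403)
  a <- random_seq(20)
  long_ext <- random_seq(50)
  mem <- mk_members(rep(paste0(a, long_ext), 3), rep(0L, 3))
  for (step in c(1L, 5L, 20L)) {
    r <- extend_window(build_msa(a, mem), stepsize = step)
    expect_equal(r$status, "extended")
    expect_lte(nchar(r$appended), step)
    expect_equal(nchar(r$appended), step)  # full coverage: exactly stepsize
  }
})

test_that("extension stops at the first under-covered column", {
  a <- random_seq(10)
  # two members cover 5 columns beyond the anchor, a third only 2
  mem <- mk_members(c(paste0(substr(a, 6, 10), "CCCCC"),
                      paste0(substr(a, 6, 10), "CCCCC"),
                      paste0(substr(a, 6, 10), "CC")),
                    rep(5L, 3))
  r <- extend_window(build_msa(a, mem), min_coverage = 3L)
  expect_equal(r$status, "extended")
  expect_identical(r$appended, "CC")  # columns 3..5 have coverage 2 < 3
})
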