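test_that("simulated genomes are reproducible and roughly uniform", {
  g1 <- simulate_genome(100, seed = 5)
  g2 <- simulate_genome(100, seed = 5)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 100L)
  expect_false(identical(simulate_genome(100, seed = 6), g1))
  big <- simulate_genome(40000, seed = 7)
  comp <- table(strsplit(big, "")[[1]]) / 40000
  expect_true(all(abs(comp - 0.25) < 0.02))  # law of large numbers
})

test_that("repeat injection copies a segment at the stated divergence", {
  g <- simulate_genome(5000, seed = 9,
                       repeat_spec = list(count = 1, length = 500,
                                          divergence = 0.02))
  g0 <- simulate_genome(5000, seed = 9)
  expect_equal(nchar(g), 5000L)
  expect_false(identical(g, g0))
})

test_that("noiseless reads are exact strand-aware genome substrings", {
  g <- simulate_genome(3000, seed = 10)
  sim <- simulate_read_pairs(g, coverage = 10, read_length = 40,
                             insert_mean = 120, insert_sd = 5,
                             subs_rate = 0, seed = 10)
  grc <- oracle_revcomp(g)
  for (i in seq_len(nrow(sim$pairs))) {
    expect_true(grepl(sim$pairs$read1[i], g, fixed = TRUE) ||
                  grepl(sim$pairs$read1[i], grc, fixed = TRUE))
    expect_true(grepl(sim$pairs$read2[i], g, fixed = TRUE) ||
                  grepl(sim$pairs$read2[i], grc, fixed = TRUE))
  }
})

test_that("the pair count and insert distribution follow the parameters", {
  g <- simulate_genome(30000, seed = 11)
  sim <- simulate_read_pairs(g, coverage = 20, read_length = 50,
                             insert_mean = 200, insert_sd = 8,
                             subs_rate = 0, seed = 11)
  expect_equal(nrow(sim$pairs), ceiling(20 * 30000 / (2 * 50)))
  ins <- sim$truth$insert
  expect_true(all(ins >= 101 & ins <= 232))  # default truncation bounds
  se <- 8 / sqrt(length(ins))
  expect_lt(abs(mean(ins) - 200), 3 * se + 0.5)  # 0.5: rounding slack
  expect_equal(sim$truth$gap_len, ins - 100L)
  expect_true(all(sim$truth$gap_len >= 1L))
})

test_that("the recorded truth gap matches the genome between the reads", {
  g <- simulate_genome(4000, seed = 12)
  sim <- simulate_read_pairs(g, coverage = 5, read_length = 30,
                             insert_mean = 100, insert_sd = 4,
                             subs_rate = 0, seed = 12)
  tr <- sim$truth
  for (i in seq_len(min(nrow(tr), 50))) {
    fwd_gap <- substr(g, tr$start[i] + 30 + 1, tr$start[i] + tr$insert[i] - 30)
    want <- if (tr$strand[i] == 0) fwd_gap else oracle_revcomp(fwd_gap)
    expect_identical(tr$gap[i], want)
    # the pair reconstructs: read1 + gap + revcomp(read2) is the molecule
    expect_identical(paste0(sim$pairs$read1[i], tr$gap[i],
                            oracle_revcomp(sim$pairs$read2[i])),
                     if (tr$strand[i] == 0) {
                       substr(g, tr$start[i] + 1, tr$start[i] + tr$insert[i])
                     } else {
                       oracle_revcomp(substr(g, tr$start[i] + 1,
                                             tr$start[i] + tr$insert[i]))
                     })
  }
})

test_that("substitution errors appear at the recorded rate and positions", {
  g <- simulate_genome(20000, seed = 13)
  sim <- simulate_read_pairs(g, coverage = 10, read_length = 100,
                             insert_mean = 300, insert_sd = 5,
                             subs_rate = 0.01, seed = 13)
  clean <- simulate_read_pairs(g, coverage = 10, read_length = 100,
                               insert_mean = 300, insert_sd = 5,
                               subs_rate = 0, seed = 13)
  # same fragments drawn (same seed): errors are the only difference
  expect_identical(sim$truth$start, clean$truth$start)
  mm <- mapply(oracle_hamming, sim$pairs$read1, clean$pairs$read1)
  expect_equal(unname(mm), sim$truth$n_err1)
  rate <- sum(sim$truth$n_err1 + sim$truth$n_err2) /
    (2 * 100 * nrow(sim$pairs))
  expect_lt(abs(rate - 0.01), 0.002)
})

test_that("simulation rejects impossible configurations", {
  g <- simulate_genome(500, seed = 1)
  expect_error(simulate_read_pairs(g, 5, 100, 220, 5,
                                   insert_bounds = c(150, 300), seed = 1),
               "2 \\* read_length")
  expect_error(simulate_read_pairs(g, 5, 50, 400, 50,
                                   insert_bounds = c(150, 600), seed = 1),
               "shorter than maximal insert")
})

test_that("gap edit distance is a unit-cost Levenshtein distance", {
  expect_equal(gap_edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(gap_edit_distance("ACGT", "ACCT"), 1L)
  expect_equal(gap_edit_distance(c("AA", "AC"), c("AA", "GC")), c(0L, 1L))
  set.seed(601)
  for (i in 1:60) {
    a <- random_seq(sample(1:60, 1))
    b <- random_seq(sample(1:60, 1))
    expect_equal(gap_edit_distance(a, b), oracle_levenshtein(a, b))
  }
})

test_that("the modified edit distance subtracts the length difference", {
  expect_equal(modified_gap_edit_distance(5L, 300L, 297L), 2L)
  expect_equal(modified_gap_edit_distance(4L, 250L, 250L), 4L)
  # two deletions: edit 2, modified 0
  a <- random_seq(40)
  b <- paste0(substr(a, 1, 10), substr(a, 13, 40))
  ed <- gap_edit_distance(b, a)
  expect_equal(ed, 2L)
  expect_equal(modified_gap_edit_distance(ed, nchar(a), nchar(b)), 0L)
  expect_error(modified_gap_edit_distance(1L, 300L, 200L), "mismatch")
})

test_that("mate placements are unique on a repeat-free genome", {
  g <- simulate_genome(20000, seed = 14)
  sim <- simulate_read_pairs(g, coverage = 2, read_length = 80,
                             insert_mean = 300, insert_sd = 10,
                             subs_rate = 0, seed = 14)
  counts <- ambiguous_mate_positions(sim$truth, g, 80, 260, 340,
                                     max_hamming = 9)
  ok <- !is.na(counts)
  expect_true(all(counts[ok] == 1L))
})

test_that("a long tandem repeat creates multiple mate placements", {
  set.seed(602)
  unit <- random_seq(600)
  g <- paste0(random_seq(2000), strrep(unit, 3), random_seq(2000))
  # a fragment whose mate lies inside the repeat: place it explicitly
  truth <- data.frame(pair = 1L, start = 2100L, insert = 700L, strand = 0L)
  counts <- ambiguous_mate_positions(truth, g, 100, 400, 1400,
                                     max_hamming = 9)
  expect_gte(counts[1, "from_read1"], 2L)
  # max_hamming = 0 reduces to exact occurrence counting
  counts0 <- ambiguous_mate_positions(truth, g, 100, 400, 1400,
                                      max_hamming = 0)
  expect_gte(counts0[1, "from_read1"], 2L)
})

test_that("evaluate_run aggregates error rates from per-pair records", {
  # fabricated results: 99 exact 300-base gaps plus one gap with 3 edits
  gaps <- vapply(1:100, function(i) random_seq(300), character(1))
  bad <- gaps[1]
  substr(bad, 10, 12) <- "AAA"
  edits1 <- oracle_levenshtein(bad, gaps[1])
  produced <- c(bad, gaps[-1])
  results <- data.frame(
    pair = 1:100,
    sequence = paste0(strrep("A", 20), produced, strrep("C", 20)),
    gap_start = 20L, gap_end = 320L,
    connected0 = TRUE, connected1 = FALSE, connected2 = FALSE,
    stringsAsFactors = FALSE)
  truth <- data.frame(pair = 1:100, gap = gaps, stringsAsFactors = FALSE)
  ev <- evaluate_run(results, truth, strict = 0)
  expect_equal(ev$summary$n_connected, 100L)
  expect_equal(ev$summary$n_error_free, 100L - (edits1 > 0))
  expect_equal(ev$summary$error_rate, sum(ev$per_pair$edit) / 30000)
  expect_equal(sum(ev$per_pair$edit), edits1)
  # id mismatch is an error
  expect_error(evaluate_run(results, truth[-1, ], strict = 0), "pair ids")
})

test_that("stratified summaries re-aggregate the per-pair records", {
  base <- tiny_sim(genome_len = 10000, seed = 15)
  res <- extend_pairs(base$idx, base$params)
  ev <- evaluate_run(res, base$sim$truth, strict = 0, genome = base$genome,
                     read_length = 100, min_length = 460, max_length = 540)
  s <- ev$summary
  expect_setequal(s$stratum, c("all", "A", "B"))
  for (cat in c("A", "B")) {
    d <- ev$per_pair[ev$per_pair$category == cat, ]
    expect_equal(s$n_connected[s$stratum == cat], nrow(d))
    if (nrow(d) > 0 && sum(d$gap_len_produced) > 0) {
      expect_equal(s$error_rate[s$stratum == cat],
                   sum(d$edit) / sum(d$gap_len_produced))
    }
  }
  expect_equal(sum(s$n_connected[s$stratum %in% c("A", "B")]),
               s$n_connected[s$stratum == "all"])
})

test_that("truth tables round-trip through TSV", {
  g <- simulate_genome(3000, seed = 16)
  sim <- simulate_read_pairs(g, 4, 40, 120, 4, subs_rate = 0.02, seed = 16)
  tmp <- tempfile()
  write_simulated_pairs(sim, tmp, format = "fastq")
  tr <- read_truth(paste0(tmp, "_truth.tsv"))
  expect_equal(tr$start, sim$truth$start)
  expect_equal(tr$gap, sim$truth$gap)
  expect_equal(tr$n_err1, sim$truth$n_err1)
})
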