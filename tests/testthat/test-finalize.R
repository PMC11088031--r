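# Handcrafted task quadruples: a molecule M on read 1's strand with reads
# of length rl at both ends. T1's finished contig is M itself; T3's is
# revcomp(M). Partial tasks are prefixes of those.
mk_mol <- function(L = 100, rl = 20, seed = 500) {
  set.seed(seed)
  M <- random_seq(L)
  list(M = M, rl = rl,
       s1 = substr(M, 1, rl),
       s2 = oracle_revcomp(substr(M, L - rl + 1, L)))
}

task <- function(contig, state, start_len, mate_pos = NA) {
  list(contig = contig, state = state, start_len = start_len,
       mate_pos = mate_pos)
}

aux_tasks <- function(mol) {
  list(T2 = task(reverse_complement(mol$s2), "stopped", mol$rl),
       T4 = task(reverse_complement(mol$s1), "stopped", mol$rl))
}

par_window <- function(min_length, max_length) {
  extension_params(insert_size = (min_length + max_length) / 2,
                   insert_sd = 5, min_length = min_length,
                   max_length = max_length)
}

test_that("agreeing directional extensions connect under every mode", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), aux$T2,
                task(oracle_revcomp(mol$M), "mate_found", 20L, 80L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_true(all(r$connected))
  expect_identical(r$sequence, mol$M)
  expect_equal(r$gap_start, 20L)
  expect_equal(r$gap_end, 80L)
  expect_identical(r$rule[3], "both_agree")
})

test_that("a single-base gap disagreement breaks strict mode 2", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  ch <- strsplit(mol$M, "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  M2 <- paste(ch, collapse = "")
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), aux$T2,
                task(oracle_revcomp(M2), "mate_found", 20L, 80L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_identical(r$connected, c(TRUE, FALSE, FALSE))
  # one tolerated mismatch reconnects mode 2
  p2 <- par_window(80, 120)
  p2$strict2_max_hamming <- 1L
  r2 <- finalize_pair(tasks, p2)
  expect_true(all(r2$connected))
})

test_that("a confirming partial extension connects under mode 1 only", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  # T3 extended over 60% of the gap (36 of 60 bases), perfectly agreeing
  t3_partial <- substr(oracle_revcomp(mol$M), 1, 20 + 36)
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), aux$T2,
                task(t3_partial, "failed", 20L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_identical(r$connected, c(TRUE, TRUE, FALSE))
  expect_identical(r$rule[2], "t1_confirmed")
  expect_identical(r$sequence, mol$M)
  # an overlap below 50% of the gap does not confirm
  t3_short <- substr(oracle_revcomp(mol$M), 1, 20 + 20)
  tasks_short <- list(tasks[[1]], aux$T2, task(t3_short, "failed", 20L),
                      aux$T4)
  r2 <- finalize_pair(tasks_short, par_window(80, 120))
  expect_identical(r2$connected, c(TRUE, FALSE, FALSE))
})

test_that("a disagreeing partial extension fails the mode-1 match check", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  bad <- paste0(substr(oracle_revcomp(mol$M), 1, 20), random_seq(36))
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), aux$T2,
                task(bad, "failed", 20L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_identical(r$connected, c(TRUE, FALSE, FALSE))
})

test_that("when only T3 finds the mate the result is its reverse complement", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  tasks <- list(task(substr(mol$M, 1, 30), "failed", 20L), aux$T2,
                task(oracle_revcomp(mol$M), "mate_found", 20L, 80L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_identical(r$connected[1], TRUE)
  expect_identical(r$rule[1], "t3")
  expect_identical(r$sequence, mol$M)  # reported on read 1's strand
  expect_identical(substr(r$sequence, 1, 20), mol$s1)
})

test_that("partial contigs merge on an exact 50-base overlap", {
  mol <- mk_mol(L = 120, seed = 501)
  aux <- aux_tasks(mol)
  c1 <- substr(mol$M, 1, 85)
  c3 <- oracle_revcomp(substr(mol$M, 36, 120))
  m <- merge_partial(c1, c3, 20L, par_window(100, 140))
  expect_equal(m$overlap, 50L)
  expect_identical(m$sequence, mol$M)
  # and finalize_pair routes through the merge under mode 0
  tasks <- list(task(c1, "failed", 20L), aux$T2,
                task(c3, "failed", 20L), aux$T4)
  r <- finalize_pair(tasks, par_window(100, 140))
  expect_identical(r$connected, c(TRUE, FALSE, FALSE))
  expect_identical(r$rule[1], "merged")
  expect_identical(r$sequence, mol$M)
})

test_that("overlaps below 40 positions never merge", {
  mol <- mk_mol(L = 120, seed = 502)
  c1 <- substr(mol$M, 1, 74)  # true overlap with the other side: 39
  c3 <- oracle_revcomp(substr(mol$M, 36, 120))
  expect_null(merge_partial(c1, c3, 20L, par_window(100, 140)))
})

test_that("the longest admissible merge overlap is chosen", {
  set.seed(503)
  X <- random_seq(32)
  Q <- paste0(strrep(X, 2), substr(X, 1, 8), random_seq(30))  # 102 bases
  c1 <- paste0(random_seq(50), substr(Q, 1, 72))              # 122 bases
  c3 <- oracle_revcomp(Q)
  # exact overlaps exist at 72 and 40 (Q starts with a period-32 block)
  m <- merge_partial(c1, c3, 20L, par_window(140, 200))
  expect_equal(m$overlap, 72L)
  expect_equal(nchar(m$sequence), 122L + 102L - 72L)
  # restricting the window to longer products forces the 40-base overlap
  m2 <- merge_partial(c1, c3, 20L, par_window(176, 200))
  expect_equal(m2$overlap, 40L)
})

test_that("merged length must agree with the insert-size window", {
  mol <- mk_mol(L = 120, seed = 504)
  c1 <- substr(mol$M, 1, 85)
  c3 <- oracle_revcomp(substr(mol$M, 36, 120))
  # true merged length is 120; a window excluding it rejects the merge
  expect_null(merge_partial(c1, c3, 20L, par_window(60, 100)))
})

test_that("outward extension is off by default and inert when tasks idle", {
  mol <- mk_mol()
  aux <- aux_tasks(mol)
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), aux$T2,
                task(oracle_revcomp(mol$M), "mate_found", 20L, 80L), aux$T4)
  r <- finalize_pair(tasks, par_window(80, 120))
  expect_equal(r$out_left, 0L)
  expect_equal(r$out_right, 0L)
  p <- par_window(80, 120)
  p$outward <- TRUE
  # T2/T4 appended nothing: result unchanged
  r2 <- finalize_pair(tasks, p)
  expect_identical(r2$sequence, mol$M)
  expect_equal(c(r2$out_left, r2$out_right), c(0L, 0L))
})

test_that("outward bases are stitched on the correct strands", {
  mol <- mk_mol(L = 100, seed = 505)
  left_flank <- random_seq(15)    # genome 5' of read 1, read-1 strand
  right_flank <- random_seq(12)   # genome 3' of the mate, read-1 strand
  t2 <- task(paste0(reverse_complement(mol$s2), right_flank), "stopped", 20L)
  t4 <- task(paste0(reverse_complement(mol$s1),
                    oracle_revcomp(left_flank)), "stopped", 20L)
  tasks <- list(task(mol$M, "mate_found", 20L, 80L), t2,
                task(oracle_revcomp(mol$M), "mate_found", 20L, 80L), t4)
  p <- par_window(80, 120)
  p$outward <- TRUE
  r <- finalize_pair(tasks, p)
  expect_identical(r$sequence, paste0(left_flank, mol$M, right_flank))
  expect_equal(c(r$out_left, r$out_right), c(15L, 12L))
  expect_equal(c(r$gap_start, r$gap_end), c(20L + 15L, 80L + 15L))
  # per-side cap
  p$outward_cap <- 10L
  r2 <- finalize_pair(tasks, p)
  expect_identical(r2$sequence,
                   paste0(substr(left_flank, 6, 15), mol$M,
                          substr(right_flank, 1, 10)))
})
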