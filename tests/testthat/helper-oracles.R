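# Shared fixtures and independent oracles for the test suite. The oracles
# are deliberately written as plain, slow R code so they share nothing with
# the C++ paths they check.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# character-level reverse complement, independent of the package's C++
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# position-by-position mismatch count
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive shift x orientation search with plain hamming distance,
# replicating the documented admissibility and tie-breaking rules
oracle_best_alignment <- function(anchor, cand, max_mm = 5L,
                                  min_frac = 0.5) {
  alen <- nchar(anchor)
  clen <- nchar(cand)
  best <- NULL
  better <- function(x, y) {
    if (x$mismatches != y$mismatches) return(x$mismatches < y$mismatches)
    if (x$overlap != y$overlap) return(x$overlap > y$overlap)
    if (x$shift != y$shift) return(x$shift < y$shift)
    x$orientation == "forward" && y$orientation == "revcomp"
  }
  for (orient in c("forward", "revcomp")) {
    cseq <- if (orient == "forward") cand else oracle_revcomp(cand)
    for (shift in 0:(alen - 1L)) {
      ov <- min(alen - shift, clen)
      if (ov < 1L || ov < min_frac * clen - 1e-9) next
      mm <- oracle_hamming(substr(anchor, shift + 1L, shift + ov),
                           substr(cseq, 1L, ov))
      if (mm > max_mm) next
      cur <- list(shift = shift, overlap = ov, mismatches = mm,
                  orientation = orient)
      if (is.null(best) || better(cur, best)) best <- cur
    }
  }
  best
}

# textbook dynamic-programming Levenshtein distance (unit costs)
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# small end-to-end simulation shared by several test files
tiny_sim <- function(genome_len = 20000, coverage = 30, read_length = 100,
                     insert_mean = 500, insert_sd = 10, subs_rate = 0,
                     seed = 7, n_tables = 48, k = 20) {
  genome <- simulate_genome(genome_len, seed = seed)
  sim <- simulate_read_pairs(genome, coverage = coverage,
                             read_length = read_length,
                             insert_mean = insert_mean,
                             insert_sd = insert_sd,
                             subs_rate = subs_rate, seed = seed)
  idx <- build_read_index(interleave_pairs(sim$pairs),
                          hash_family(n_tables, k, seed))
  list(genome = genome, sim = sim, idx = idx,
       params = extension_params(insert_mean, insert_sd))
}
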