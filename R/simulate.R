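#' Simulate a reference genome
#'
#' Uniform-random ACGT sequence, optionally with injected inexact repeats
#' for stress-testing repeat handling: `repeat_spec` copies a random source
#' segment to `count` random destinations, mutating each copy at the given
#' divergence rate.
#'
#' @param length Genome length in bases.
#' @param seed RNG seed; the genome is deterministic per seed.
#' @param repeat_spec `NULL`, or a list with `count`, `length` and
#'   `divergence` (per-base substitution rate of each copy, e.g. 0.02).
#' @return A character scalar.
#' @examples
#' g <- simulate_genome(1000, seed = 42)
#' @export
simulate_genome <- function(length, seed = 1L, repeat_spec = NULL) {
  stopifnot(length >= 1)
  local_seed(seed, {
    bases <- c("A", "C", "G", "T")
    g <- sample(bases, length, replace = TRUE)
    if (!is.null(repeat_spec)) {
      stopifnot(all(c("count", "length", "divergence") %in% names(repeat_spec)))
      rl <- repeat_spec$length
      if (rl > length) stop("repeat length exceeds genome length")
      src <- sample.int(length - rl + 1L, 1L)
      unit <- g[src:(src + rl - 1L)]
      for (i in seq_len(repeat_spec$count)) {
        copy <- unit
        nmut <- rbinom(1L, rl, repeat_spec$divergence)
        if (nmut > 0) {
          pos <- sample.int(rl, nmut)
          copy[pos] <- vapply(copy[pos], function(b) {
            sample(setdiff(bases, b), 1L)
          }, character(1))
        }
        dst <- sample.int(length - rl + 1L, 1L)
        g[dst:(dst + rl - 1L)] <- copy
      }
    }
    paste(g, collapse = "")
  })
}

# Per-base substitution errors, i.i.d. at rate `rate`; the substituted base
# is drawn uniformly from the three alternatives.
inject_errors <- function(reads, rate) {
  if (rate <= 0) {
    return(list(reads = reads, n_errors = integer(length(reads)),
                positions = vector("list", length(reads))))
  }
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  positions <- vector("list", length(reads))
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sort(sample.int(lens[i], n_err[i]))
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    offs <- sample.int(3L, n_err[i], replace = TRUE)
    old <- match(chars[pos], bases) - 1L
    chars[pos] <- bases[((old + offs) %% 4L) + 1L]
    reads[i] <- paste(chars, collapse = "")
    positions[[i]] <- pos
  }
  list(reads = reads, n_errors = n_err, positions = positions)
}

#' Simulate Illumina-like paired-end reads with known truth
#'
#' Emulates a minimal paired-end run: `ceiling(coverage * G / (2 *
#' read_length))` fragments placed uniformly on the genome, insert sizes
#' drawn from a normal distribution truncated to `insert_bounds` (the
#' insert includes both read lengths), each pair sequenced from a random
#' strand (read 2 is the reverse complement of the fragment's far end on
#' read 1's strand), and i.i.d. per-base substitution errors at
#' `subs_rate`. Only substitutions are simulated — the dominant error mode
#' of the targeted platform; no indels and no quality-profile emulation.
#'
#' The default bounds `[max(2 * read_length + 1, mean - 4 * sd),
#' mean + 4 * sd]` exclude overlapping pairs, which the extension workflow
#' does not consider.
#'
#' @param genome Character scalar (e.g. from [simulate_genome()]).
#' @param coverage Target coverage (default 30).
#' @param read_length Read length in bases (both mates).
#' @param insert_mean,insert_sd Insert-size distribution.
#' @param insert_bounds Length-2 numeric, inclusive truncation bounds;
#'   `NULL` for the default above.
#' @param subs_rate Per-base substitution error rate (default 0).
#' @param seed RNG seed.
#' @return A list with `pairs` (data.frame `pair`, `read1`, `read2`) and
#'   `truth` (data.frame `pair`, `start` (0-based fragment start), `insert`,
#'   `strand` (0 = read 1 forward), `gap` (true gap sequence on read 1's
#'   strand), `gap_len`, `n_err1`, `n_err2`, `err_pos1`, `err_pos2`
#'   (comma-separated 1-based positions)), plus the generating `params`.
#' @export
simulate_read_pairs <- function(genome, coverage = 30, read_length = 100L,
                                insert_mean = 500, insert_sd = 10,
                                insert_bounds = NULL, subs_rate = 0,
                                seed = 1L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  rl <- as.integer(read_length)
  if (is.null(insert_bounds)) {
    insert_bounds <- c(max(2L * rl + 1L, round(insert_mean - 4 * insert_sd)),
                       round(insert_mean + 4 * insert_sd))
  }
  lo <- as.integer(insert_bounds[1])
  hi <- as.integer(insert_bounds[2])
  if (lo < 2L * rl + 1L) {
    stop("insert lower bound must exceed 2 * read_length (no overlapping ",
         "pairs): ", lo, " <= ", 2L * rl)
  }
  if (lo > hi) stop("invalid insert bounds")
  if (G < hi) stop("genome (", G, " bp) shorter than maximal insert ", hi)
  n <- as.integer(ceiling(coverage * G / (2 * rl)))

  local_seed(seed, {
    ins <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
    bad <- which(ins < lo | ins > hi)
    guard <- 0L
    while (length(bad) > 0L) {
      ins[bad] <- as.integer(round(rnorm(length(bad), insert_mean, insert_sd)))
      bad <- bad[ins[bad] < lo | ins[bad] > hi]
      guard <- guard + 1L
      if (guard > 10000L) stop("insert bounds reject nearly all draws")
    }
    start <- as.integer(floor(runif(n) * (G - ins + 1)))  # 0-based
    strand <- rbinom(n, 1L, 0.5)

    left <- substring(genome, start + 1L, start + rl)
    right_rc <- cpp_revcomp(substring(genome, start + ins - rl + 1L,
                                      start + ins))
    gap_fwd <- substring(genome, start + rl + 1L, start + ins - rl)

    read1 <- ifelse(strand == 0L, left, right_rc)
    read2 <- ifelse(strand == 0L, right_rc, left)
    gap <- ifelse(strand == 0L, gap_fwd, cpp_revcomp(gap_fwd))

    e1 <- inject_errors(read1, subs_rate)
    e2 <- inject_errors(read2, subs_rate)
    pos_str <- function(p) {
      vapply(p, function(x) paste(x, collapse = ","), character(1))
    }
    list(
      pairs = data.frame(pair = seq_len(n), read1 = e1$reads,
                         read2 = e2$reads, stringsAsFactors = FALSE),
      truth = data.frame(pair = seq_len(n), start = start, insert = ins,
                         strand = strand, gap = gap,
                         gap_len = ins - 2L * rl,
                         n_err1 = e1$n_errors, n_err2 = e2$n_errors,
                         err_pos1 = pos_str(e1$positions),
                         err_pos2 = pos_str(e2$positions),
                         stringsAsFactors = FALSE),
      params = list(coverage = coverage, read_length = rl,
                    insert_mean = insert_mean, insert_sd = insert_sd,
                    insert_bounds = c(lo, hi), subs_rate = subs_rate,
                    seed = seed, genome_length = G, n_pairs = n)
    )
  })
}

#' Write simulated pairs as FASTQ/FASTA plus a truth table
#'
#' Creates `<prefix>_1` and `<prefix>_2` read files (constant quality `I`
#' for FASTQ) and `<prefix>_truth.tsv` with the columns of
#' `sim$truth`.
#'
#' @param sim A [simulate_read_pairs()] result.
#' @param prefix Output path prefix.
#' @param format `"fastq"` or `"fasta"`.
#' @return Invisibly, the written paths.
#' @export
write_simulated_pairs <- function(sim, prefix, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ext <- paste0(".", format)
  p1 <- paste0(prefix, "_1", ext)
  p2 <- paste0(prefix, "_2", ext)
  pt <- paste0(prefix, "_truth.tsv")
  ids <- sprintf("sim_pair_%d", sim$pairs$pair)
  write_one <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    if (format == "fastq") {
      q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
      Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    } else {
      Biostrings::writeXStringSet(x, path, format = "fasta")
    }
  }
  write_one(sim$pairs$read1, p1)
  write_one(sim$pairs$read2, p2)
  utils::write.table(sim$truth, pt, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(reads_1 = p1, reads_2 = p2, truth = pt))
}

#' Read a truth table written by [write_simulated_pairs()]
#'
#' @param path Path to the `_truth.tsv` file.
#' @return The truth data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(err_pos1 = "character",
                                   err_pos2 = "character"))
}
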