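#' Extend every read pair of an index into pseudo-long reads
#'
#' Phase 2 of the workflow: runs the four-task extension of every pair in
#' the (interleaved) index and finalizes each under all three strict modes
#' at once — the modes only differ in how the finished tasks are combined,
#' so a single task run yields `connected0`, `connected1` and `connected2`.
#'
#' @param index A `KmerIndex` built over interleaved paired reads
#'   (reads `2*i - 1` and `2*i` form pair `i`).
#' @param params An [extension_params()] list; `min_length`/`max_length`
#'   are resolved from the insert-size estimate and the longest read when
#'   not set explicitly.
#' @param verbose Print progress every 10,000 pairs.
#' @return A data.frame with one row per pair: `pair`, task states and
#'   contig lengths (`t1_state`, `t3_state`, `t1_len`, `t3_len`),
#'   per-mode connection status and provenance (`connected0/1/2`,
#'   `rule0/1/2`), the result `sequence` (read 1's strand; `NA` when
#'   nothing connected), `gap_start`/`gap_end` (0-based half-open
#'   coordinates of the filled gap within `sequence`), and
#'   `out_left`/`out_right` (outward bases, 0 unless `outward = TRUE`).
#' @examples
#' genome <- simulate_genome(5000, seed = 7)
#' sim <- simulate_read_pairs(genome, coverage = 25, read_length = 70,
#'                            insert_mean = 220, insert_sd = 5, seed = 7)
#' idx <- build_read_index(interleave_pairs(sim$pairs),
#'                         hash_family(n_tables = 16, k = 16, seed = 7))
#' res <- extend_pairs(idx, extension_params(220, 5))
#' mean(res$connected0)
#' @export
extend_pairs <- function(index, params, verbose = FALSE) {
  stopifnot(inherits(index, "KmerIndex"))
  if (index$n_reads %% 2 != 0) {
    stop("index must hold an even number of reads (interleaved pairs)")
  }
  params <- resolve_params(params,
                           read_lengths = rep(index$read_length_max, 2L))
  out <- cpp_extend_all(index$ptr, params, isTRUE(verbose))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out <- cbind(pair = seq_len(nrow(out)), out)
  attr(out, "params") <- params
  out
}

#' Interleave the two reads of each pair into one vector
#'
#' @param pairs A data.frame with `read1` and `read2` columns.
#' @return Character vector `read1[1], read2[1], read1[2], ...`.
#' @export
interleave_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("read1", "read2") %in% names(pairs)))
  out <- character(2L * nrow(pairs))
  out[c(TRUE, FALSE)] <- pairs$read1
  out[c(FALSE, TRUE)] <- pairs$read2
  out
}

# FASTA if the first non-empty byte is '>', FASTQ for '@'.
sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("empty input file: ", path)
    if (nzchar(trimws(line))) break
  }
  first <- substr(trimws(line), 1L, 1L)
  if (first == ">") return("fasta")
  if (first == "@") return("fastq")
  stop("cannot determine format of ", path, " (expected FASTA or FASTQ)")
}

read_seq_file <- function(path) {
  fmt <- sniff_format(path)
  if (fmt == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    list(id = names(x), seq = as.character(unname(x)), qual = NULL)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(id = names(x), seq = as.character(unname(x)),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
}

#' Read paired sequencing reads from FASTQ/FASTA
#'
#' Accepts two mate files or a single interleaved file (mate 1 first in
#' each record pair). Multi-line FASTA and gzip-compressed inputs are
#' handled; FASTQ qualities are carried along unchanged.
#'
#' @param file1 Path to the mate-1 file, or to the interleaved file when
#'   `file2` is `NULL`.
#' @param file2 Path to the mate-2 file, or `NULL` for interleaved input.
#' @return A data.frame with columns `pair`, `id` (mate-1 record id),
#'   `read1`, `read2` and, for FASTQ input, `qual1`/`qual2`.
#' @export
read_pairs <- function(file1, file2 = NULL) {
  if (!file.exists(file1)) stop("input file not found: ", file1)
  a <- read_seq_file(file1)
  if (is.null(file2)) {
    n <- length(a$seq)
    if (n %% 2L != 0L) {
      stop("interleaved input holds ", n, " records (odd); mate files are ",
           "out of sync or a record is missing")
    }
    odd <- seq(1L, n, by = 2L)
    out <- data.frame(pair = seq_len(n %/% 2L), id = a$id[odd],
                      read1 = a$seq[odd], read2 = a$seq[odd + 1L],
                      stringsAsFactors = FALSE)
    if (!is.null(a$qual)) {
      out$qual1 <- a$qual[odd]
      out$qual2 <- a$qual[odd + 1L]
    }
    return(out)
  }
  if (!file.exists(file2)) stop("input file not found: ", file2)
  b <- read_seq_file(file2)
  if (length(a$seq) != length(b$seq)) {
    stop("mate files out of sync: ", length(a$seq), " vs ", length(b$seq),
         " records (first difference at record ",
         min(length(a$seq), length(b$seq)) + 1L, ")")
  }
  out <- data.frame(pair = seq_along(a$seq), id = a$id, read1 = a$seq,
                    read2 = b$seq, stringsAsFactors = FALSE)
  if (!is.null(a$qual) && !is.null(b$qual)) {
    out$qual1 <- a$qual
    out$qual2 <- b$qual
  }
  out
}

#' Write extension results to disk
#'
#' Connected pseudo-long reads are written as FASTA
#' (`<prefix>_extended.fasta`) with headers of the form
#' `pair=<i> status=connected strict=<mode> rule=<rule>
#' gap_start=<s> gap_end=<e>` (coordinates 0-based, half-open). Unconnected
#' pairs are passed through unchanged to `<prefix>_remaining_1` /
#' `_remaining_2` (FASTQ when input qualities are available, FASTA
#' otherwise). Consensus-derived bases have no defined quality, so
#' connected products are always FASTA.
#'
#' @param results An [extend_pairs()] data.frame.
#' @param pairs The matching [read_pairs()] data.frame (originals and
#'   qualities for the remaining output).
#' @param prefix Output path prefix.
#' @param strict Strict mode whose connection status selects the output
#'   (0, 1 or 2).
#' @return Invisibly, a named list of the written paths and counts.
#' @export
write_results <- function(results, pairs, prefix, strict = 0L) {
  stopifnot(is.data.frame(results), is.data.frame(pairs),
            nrow(results) == nrow(pairs), strict %in% 0:2)
  connected <- results[[paste0("connected", strict)]]
  rule <- results[[paste0("rule", strict)]]
  ext_path <- paste0(prefix, "_extended.fasta")

  con_idx <- which(connected)
  ext <- Biostrings::DNAStringSet(results$sequence[con_idx])
  names(ext) <- sprintf(
    "pair=%d status=connected strict=%d rule=%s gap_start=%d gap_end=%d",
    results$pair[con_idx], as.integer(strict), rule[con_idx],
    results$gap_start[con_idx], results$gap_end[con_idx])
  Biostrings::writeXStringSet(ext, ext_path)

  rem_idx <- which(!connected)
  has_qual <- all(c("qual1", "qual2") %in% names(pairs))
  rem_fmt <- if (has_qual) "fastq" else "fasta"
  rem_ext <- if (has_qual) ".fastq" else ".fasta"
  rem1_path <- paste0(prefix, "_remaining_1", rem_ext)
  rem2_path <- paste0(prefix, "_remaining_2", rem_ext)
  write_one <- function(seqs, ids, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    if (has_qual) {
      Biostrings::writeXStringSet(x, path, format = "fastq",
                                  qualities = Biostrings::BStringSet(quals))
    } else {
      Biostrings::writeXStringSet(x, path, format = "fasta")
    }
  }
  ids <- if ("id" %in% names(pairs)) pairs$id[rem_idx] else
    paste0("pair", pairs$pair[rem_idx])
  write_one(pairs$read1[rem_idx], ids,
            if (has_qual) pairs$qual1[rem_idx], rem1_path)
  write_one(pairs$read2[rem_idx], ids,
            if (has_qual) pairs$qual2[rem_idx], rem2_path)
  invisible(list(extended = ext_path, remaining_1 = rem1_path,
                 remaining_2 = rem2_path, n_connected = length(con_idx),
                 n_remaining = length(rem_idx), format_remaining = rem_fmt))
}

#' Parse a header written by [write_results()]
#'
#' @param header A FASTA record id from the extended output.
#' @return A list with `pair`, `strict`, `rule`, `gap_start`, `gap_end`.
#' @export
parse_extended_header <- function(header) {
  field <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", header)
  list(pair = as.integer(field("pair")),
       strict = as.integer(field("strict")),
       rule = field("rule"),
       gap_start = as.integer(field("gap_start")),
       gap_end = as.integer(field("gap_end")))
}

#' Run the full extension pipeline on read files
#'
#' Two phases: (1) parse the inputs and build the minhash index over all
#' reads; (2) extend every pair and, when `output_prefix` is given, write
#' the connected pseudo-long reads and the remaining pairs. Results are
#' deterministic for a fixed seed and identical regardless of `threads`
#' (pairs are processed in a fixed order).
#'
#' @param file1,file2 Input files, as in [read_pairs()].
#' @param insert_size,insert_sd Insert-size mean and standard deviation.
#' @param output_prefix Path prefix for outputs, or `NULL` to skip writing.
#' @param strict Strict mode for the written output (0, 1 or 2).
#' @param n_tables,k,seed Minhash index configuration
#'   (see [hash_family()]).
#' @param params An [extension_params()] list; by default constructed from
#'   `insert_size`/`insert_sd`.
#' @param verbose Print phase progress.
#' @return A list with `summary` (pair counts overall, per strict mode and
#'   per provenance rule) and `results` (the [extend_pairs()] data.frame).
#' @export
run_pipeline <- function(file1, file2 = NULL, insert_size, insert_sd,
                         output_prefix = NULL, strict = 0L,
                         n_tables = 48L, k = 20L, seed = 1L,
                         params = extension_params(insert_size, insert_sd),
                         verbose = FALSE) {
  stopifnot(strict %in% 0:2)
  pairs <- read_pairs(file1, file2)
  if (verbose) message("phase 1: indexing ", 2L * nrow(pairs), " reads")
  idx <- build_read_index(interleave_pairs(pairs),
                          hash_family(n_tables, k, seed),
                          max_bucket_size = params$max_bucket_size)
  if (verbose) message("phase 2: extending ", nrow(pairs), " pairs")
  results <- extend_pairs(idx, params, verbose = verbose)
  written <- NULL
  if (!is.null(output_prefix)) {
    written <- write_results(results, pairs, output_prefix, strict = strict)
  }
  rules <- results[[paste0("rule", strict)]]
  summary <- list(
    n_pairs = nrow(results),
    n_connected = sum(results[[paste0("connected", strict)]]),
    n_unconnected = sum(!results[[paste0("connected", strict)]]),
    strict = as.integer(strict),
    connected_by_mode = c(strict0 = sum(results$connected0),
                          strict1 = sum(results$connected1),
                          strict2 = sum(results$connected2)),
    rule_counts = table(rules[!is.na(rules)]),
    n_short_skipped = idx$n_short_skipped,
    files = written
  )
  if (verbose) {
    message(sprintf("connected %d / %d pairs (strict %d)",
                    summary$n_connected, summary$n_pairs, strict))
  }
  list(summary = summary, results = results)
}
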