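#' Define a minhash hash-function family
#'
#' A family of `n_tables` independently seeded 64-bit integer mixers applied
#' to the 2-bit packed canonical form of each k-mer (the lexicographic
#' minimum of a k-mer and its reverse complement, so one query retrieves
#' candidates from both strands). The per-table seeds are derived
#' deterministically from `seed`, making signatures and indexes reproducible.
#'
#' @param n_tables Number of hash functions / hash tables (default 48).
#' @param k K-mer length, 1..32 (default 20).
#' @param seed Integer base seed for the family.
#' @return A `HashFamily` object.
#' @examples
#' fam <- hash_family(n_tables = 8, k = 5, seed = 1)
#' compute_signature("ACGTACGTAC", fam)
#' @export
hash_family <- function(n_tables = 48L, k = 20L, seed = 1L) {
  n_tables <- as.integer(n_tables)
  k <- as.integer(k)
  seed <- as.numeric(seed)
  if (is.na(n_tables) || n_tables < 1L) stop("n_tables must be >= 1")
  if (is.na(k) || k < 1L || k > 32L) stop("k must be in [1, 32]")
  structure(
    list(h = n_tables, k = k, seed = seed,
         seeds = cpp_family_seeds(n_tables, k, seed)),
    class = "HashFamily"
  )
}

#' @export
print.HashFamily <- function(x, ...) {
  cat(sprintf("HashFamily: %d hash functions, k = %d, seed = %s\n",
              x$h, x$k, format(x$seed)))
  invisible(x)
}

#' Minhash signature of a sequence
#'
#' For each hash function of the family, the minimum hash value over all
#' canonical k-mers of the sequence. Two sequences sharing the minimizing
#' k-mer under some hash function receive the same signature entry there and
#' will meet in that hash table.
#'
#' @param x DNA string or `EncodedSequence` of length >= k.
#' @param family A [hash_family()].
#' @return Character vector of `n_tables` zero-padded 16-digit hex values
#'   (lexicographic order equals numeric order).
#' @export
compute_signature <- function(x, family) {
  stopifnot(inherits(family, "HashFamily"))
  x <- as_seq_char(x)
  if (nchar(x) < family$k) {
    stop("sequence shorter than k (", nchar(x), " < ", family$k, ")")
  }
  cpp_signature(x, family$h, family$k, family$seed)
}

#' Hash values of a single k-mer
#'
#' All `n_tables` hash values of one canonical k-mer, computed directly
#' (without the rolling scan used by [compute_signature()]). Mostly useful
#' for inspecting or verifying signatures.
#'
#' @param kmer DNA string of exactly `k` bases.
#' @inheritParams compute_signature
#' @return Character vector of 16-digit hex values.
#' @export
kmer_hash_values <- function(kmer, family) {
  stopifnot(inherits(family, "HashFamily"))
  kmer <- as_seq_char(kmer)
  if (nchar(kmer) != family$k) stop("kmer must have exactly k bases")
  cpp_hash_kmer(kmer, family$h, family$k, family$seed)
}

#' Build the minhash k-mer index over a read set
#'
#' Computes the minhash signature of every read and inserts the pair
#' (signature value, read id) into each of the `n_tables` hash tables.
#' Reads shorter than k are skipped (counted in `n_short_skipped`) and are
#' never retrieved or extended. Buckets larger than `max_bucket_size` ids
#' (arising from high-copy repeats) are truncated at build time and counted
#' in `n_capped_keys`.
#'
#' @param reads Character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`). For paired data, interleave the mates:
#'   reads `2*i - 1` and `2*i` form pair `i`.
#' @param family A [hash_family()].
#' @param max_bucket_size Maximum ids stored per hash-table key.
#' @return A `KmerIndex` object (holds external state; cannot be serialized).
#' @examples
#' idx <- build_read_index(c("ACGTACGTACGT", "CGTACGTACGTA"),
#'                         hash_family(n_tables = 4, k = 6, seed = 1))
#' query_candidates("ACGTACGTACGT", idx)
#' @export
build_read_index <- function(reads, family = hash_family(),
                             max_bucket_size = 1000L) {
  stopifnot(inherits(family, "HashFamily"))
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads))
  if (length(reads) == 0L) stop("read set must be non-empty")
  built <- cpp_build_index(reads, family$h, family$k, family$seed,
                           as.integer(max_bucket_size))
  structure(
    list(ptr = built$ptr, family = family, n_reads = built$n_reads,
         n_short_skipped = built$n_short_skipped,
         n_capped_keys = built$n_capped_keys,
         read_length_max = max(nchar(reads))),
    class = "KmerIndex"
  )
}

#' @export
print.KmerIndex <- function(x, ...) {
  cat(sprintf(
    "KmerIndex: %d reads, %d tables, k = %d (%d short reads skipped, %d capped keys)\n",
    x$n_reads, x$family$h, x$family$k, x$n_short_skipped, x$n_capped_keys))
  invisible(x)
}

#' Retrieve candidate read ids for a query sequence
#'
#' Computes the query's minhash signature and unions the id lists found at
#' the corresponding key of every hash table: the reads likely to share a
#' k-mer with the query. An indexed read queried with its own full sequence
#' always retrieves its own id.
#'
#' @param x DNA string or `EncodedSequence` of length >= k.
#' @param index A [build_read_index()] result.
#' @return Sorted integer vector of 1-based read ids (deduplicated).
#' @export
query_candidates <- function(x, index) {
  stopifnot(inherits(index, "KmerIndex"))
  x <- as_seq_char(x)
  if (nchar(x) < index$family$k) {
    stop("sequence shorter than k (", nchar(x), " < ", index$family$k, ")")
  }
  cpp_query(index$ptr, x)
}

#' Look up one hash-table key directly
#'
#' @param index A `KmerIndex`.
#' @param table Table number, 1..n_tables.
#' @param key 16-digit hex key (one entry of a [compute_signature()]).
#' @return Integer vector of 1-based read ids stored under that key.
#' @keywords internal
#' @export
index_lookup <- function(index, table, key) {
  stopifnot(inherits(index, "KmerIndex"))
  cpp_index_lookup(index$ptr, as.integer(table), key)
}

#' Fetch read sequences stored in an index
#'
#' @param index A `KmerIndex`.
#' @param ids 1-based read ids.
#' @return Character vector of sequences (after ambiguity replacement).
#' @keywords internal
#' @export
index_reads <- function(index, ids) {
  stopifnot(inherits(index, "KmerIndex"))
  cpp_index_reads(index$ptr, as.integer(ids))
}
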