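#' Edit distance between a produced gap and the true gap
#'
#' Plain Levenshtein distance (unit costs), the gap-accuracy unit of the
#' evaluation: it charges both substitution errors and length errors of the
#' filled gap.
#'
#' @param produced Character vector of produced gap sequences.
#' @param truth Character vector of true gap sequences (same length).
#' @return Integer vector of edit distances.
#' @examples
#' gap_edit_distance("ACGT", "ACCT")  # 1
#' @export
gap_edit_distance <- function(produced, truth) {
  stopifnot(length(produced) == length(truth))
  out <- integer(length(produced))
  differ <- which(produced != truth)
  for (i in differ) {
    out[i] <- as.integer(utils::adist(produced[i], truth[i]))
  }
  out
}

#' Modified edit distance: substitution-type errors only
#'
#' Subtracts the absolute difference between expected and produced gap
#' length from the edit distance, isolating wrong-base errors from
#' wrong-length errors. Never negative, since an edit distance is at least
#' the length difference.
#'
#' @param edit_distance Integer vector from [gap_edit_distance()].
#' @param expected_len,produced_len Gap lengths.
#' @return Integer vector.
#' @export
modified_gap_edit_distance <- function(edit_distance, expected_len,
                                       produced_len) {
  out <- edit_distance - abs(expected_len - produced_len)
  if (any(out < 0, na.rm = TRUE)) {
    stop("edit distance smaller than the length difference; inputs mismatch")
  }
  out
}

#' Count admissible mate placements for simulated pairs
#'
#' For each pair, scans the allowed pseudo-long read length window
#' `[min_length, max_length]` from each read's true start and counts the
#' positions where the (error-free) mate sequence places with hamming
#' distance at most `max_hamming`. Pairs where either direction admits more
#' than one placement are the "ambiguous mate" pairs (category A) that
#' dominate length errors; on a repeat-free random genome essentially all
#' pairs count exactly 1. With `max_hamming = 0` this reduces to
#' exact-occurrence counting.
#'
#' @param truth A [simulate_read_pairs()] truth data.frame (or rows of it).
#' @param genome The genome the pairs were simulated from.
#' @param read_length Read length used in the simulation.
#' @param min_length,max_length Allowed pseudo-long read length window.
#' @param max_hamming Maximum hamming distance of a placement (default 9).
#' @return An integer matrix with one row per pair and columns
#'   `from_read1`, `from_read2` (placement counts; `NA` if the true mate
#'   window leaves the genome).
#' @export
ambiguous_mate_positions <- function(truth, genome, read_length,
                                     min_length, max_length,
                                     max_hamming = 9L) {
  stopifnot(is.data.frame(truth),
            all(c("start", "insert", "strand") %in% names(truth)))
  rl <- as.integer(read_length)
  out <- cpp_count_mate_placements(genome, as.integer(truth$start),
                                   as.integer(truth$insert),
                                   as.integer(truth$strand), rl, rl,
                                   as.integer(min_length),
                                   as.integer(max_length),
                                   as.integer(max_hamming))
  colnames(out) <- c("from_read1", "from_read2")
  out
}

#' Evaluate an extension run against simulation truth
#'
#' Joins the extension results with the simulator truth by pair id,
#' extracts each connected pair's filled gap, and aggregates the gap
#' accuracy metrics: `error_rate` (sum of edit distances over the sum of
#' produced gap lengths), `modified_error_rate` (same, with length
#' differences subtracted from the edits), connected and error-free counts.
#' When `genome` is supplied, pairs are additionally stratified by mate
#' ambiguity: category A pairs admit multiple mate placements in the
#' allowed window (hamming <= `max_hamming`), category B are the rest.
#'
#' @param results An [extend_pairs()] data.frame.
#' @param truth The matching [simulate_read_pairs()] truth data.frame.
#' @param strict Strict mode whose connections are evaluated (0, 1 or 2).
#' @param genome Optional genome string for the ambiguity stratification.
#' @param read_length,min_length,max_length Needed with `genome`; the
#'   simulation read length and the run's length window.
#' @param max_hamming Ambiguity placement tolerance (default 9).
#' @return A list with `per_pair` (pair, produced/expected gap lengths,
#'   `edit`, `modified`, `category`) and `summary` (one row per stratum:
#'   `n_connected`, `n_error_free`, `error_rate`, `modified_error_rate`).
#' @export
evaluate_run <- function(results, truth, strict = 0L, genome = NULL,
                         read_length = NULL, min_length = NULL,
                         max_length = NULL, max_hamming = 9L) {
  stopifnot(is.data.frame(results), is.data.frame(truth), strict %in% 0:2)
  if (!setequal(results$pair, truth$pair)) {
    stop("results and truth disagree on pair ids")
  }
  truth <- truth[match(results$pair, truth$pair), ]
  connected <- results[[paste0("connected", strict)]]
  idx <- which(connected)
  # outward bases (if any) are excluded: the filled gap is the unit of
  # evaluation
  produced <- substr(results$sequence[idx], results$gap_start[idx] + 1L,
                     results$gap_end[idx])
  produced[is.na(produced)] <- ""
  expected <- truth$gap[idx]
  edit <- gap_edit_distance(produced, expected)
  modified <- modified_gap_edit_distance(edit, nchar(expected),
                                         nchar(produced))

  category <- rep(NA_character_, length(idx))
  if (!is.null(genome)) {
    if (is.null(read_length) || is.null(min_length) || is.null(max_length)) {
      stop("genome stratification needs read_length, min_length, max_length")
    }
    counts <- ambiguous_mate_positions(truth[idx, , drop = FALSE], genome,
                                       read_length, min_length, max_length,
                                       max_hamming)
    multi <- apply(counts, 1L, function(r) any(r > 1L, na.rm = TRUE))
    category <- ifelse(multi, "A", "B")
  }

  per_pair <- data.frame(pair = results$pair[idx],
                         gap_len_produced = nchar(produced),
                         gap_len_expected = nchar(expected),
                         edit = edit, modified = modified,
                         category = category, stringsAsFactors = FALSE)
  summarize <- function(d, label) {
    data.frame(
      stratum = label, n_connected = nrow(d),
      n_error_free = sum(d$edit == 0L),
      error_rate = if (sum(d$gap_len_produced) > 0) {
        sum(d$edit) / sum(d$gap_len_produced)
      } else NA_real_,
      modified_error_rate = if (sum(d$gap_len_produced) > 0) {
        sum(d$modified) / sum(d$gap_len_produced)
      } else NA_real_,
      stringsAsFactors = FALSE)
  }
  summary <- summarize(per_pair, "all")
  if (!is.null(genome)) {
    summary <- rbind(summary,
                     summarize(per_pair[per_pair$category == "A", ], "A"),
                     summarize(per_pair[per_pair$category == "B", ], "B"))
  }
  summary$n_pairs_total <- nrow(results)
  list(per_pair = per_pair, summary = summary)
}
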