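#' Create the four extension tasks of a read pair
#'
#' For a pair (S1, S2) with reverse complements RC1, RC2, four tasks are
#' created: T1 (primary) starts from S1 and extends until it reaches RC2;
#' T3 (primary) starts from S2 with target RC1. T2 and T4 are auxiliary
#' tasks starting from RC2 and RC1 respectively; they carry no target and
#' exist to confirm candidate reads through their mates (and to supply the
#' optional outward extension). T1/T2 and T3/T4 are partner tasks.
#'
#' @param read1,read2 DNA strings or `EncodedSequence` objects.
#' @return A named list of four task lists (`T1`..`T4`), each with `label`,
#'   `role` (`"primary"`/`"auxiliary"`), `contig` (the starting sequence),
#'   `window`, `mate_target` (primary only), `state` (`"active"`) and
#'   `partner`.
#' @export
make_tasks <- function(read1, read2) {
  s1 <- as_seq_char(read1)
  s2 <- as_seq_char(read2)
  rc1 <- cpp_revcomp(s1)
  rc2 <- cpp_revcomp(s2)
  task <- function(label, role, start, target, partner) {
    list(label = label, role = role, contig = start, window = start,
         mate_target = target, state = "active", mate_pos = NA_integer_,
         partner = partner)
  }
  list(
    T1 = task("T1", "primary", s1, rc2, "T2"),
    T2 = task("T2", "auxiliary", rc2, NULL, "T1"),
    T3 = task("T3", "primary", s2, rc1, "T4"),
    T4 = task("T4", "auxiliary", rc1, NULL, "T3")
  )
}

#' Gather and align the candidate batch for an extension window
#'
#' Queries the minhash index with the window, aligns every retrieved read
#' with [best_alignment()], and drops reads without an admissible placement.
#' The ids in `exclude` (typically the extending pair's own two reads) are
#' removed before alignment.
#'
#' @param index A `KmerIndex`.
#' @param window The current window sequence (length >= k).
#' @param exclude Integer read ids excluded as self-hits.
#' @param max_mismatches,min_overlap_frac Placement constraints.
#' @return A data.frame with `id`, `shift`, `overlap`, `mismatches`,
#'   `orientation` and `O` (relative overlap `overlap / nchar(window)`),
#'   plus the full retrieved id set in attribute `"retrieved"`.
#' @export
gather_candidates <- function(index, window, exclude = integer(),
                              max_mismatches = 5L, min_overlap_frac = 0.5) {
  stopifnot(inherits(index, "KmerIndex"))
  window <- as_seq_char(window)
  ids <- setdiff(query_candidates(window, index), as.integer(exclude))
  rows <- lapply(ids, function(i) {
    a <- best_alignment(window, index_reads(index, i),
                        max_mismatches = max_mismatches,
                        min_overlap_frac = min_overlap_frac)
    if (is.null(a)) return(NULL)
    data.frame(id = i, shift = a$shift, overlap = a$overlap,
               mismatches = a$mismatches, orientation = a$orientation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(id = integer(), shift = integer(), overlap = integer(),
                      mismatches = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  }
  out$O <- out$overlap / nchar(window)
  attr(out, "retrieved") <- ids
  out
}

#' Pair-aware overlap filter for a candidate batch
#'
#' Candidates whose mate occurs in the partner task's batch are kept
#' unconditionally (flagged `is_paired_rescue`). Over the remaining,
#' unpaired candidates the threshold `T = max_i(floor(O_i * 10) / 10)` is
#' computed from the relative overlaps `O_i = overlap / |S|`, and unpaired
#' candidates with `O_i < T` are dropped. When the partner task has
#' terminated (`partner_batch = NULL`), every candidate is treated as
#' unpaired.
#'
#' For interleaved pair storage (reads `2*i - 1` and `2*i` form pair `i`),
#' the mate of a read id is given by [mate_id()].
#'
#' @param batch A data.frame with columns `id` (read id) and `overlap`
#'   (alignment overlap length in bases).
#' @param anchor_len Window length `|S|`.
#' @param partner_batch The partner task's batch (same format), or `NULL`.
#' @return The filtered batch with an added logical `is_paired_rescue`
#'   column and the threshold in attribute `"threshold"` (`NA` when all
#'   candidates were rescued).
#' @export
filter_candidates <- function(batch, anchor_len, partner_batch = NULL) {
  stopifnot(is.data.frame(batch), all(c("id", "overlap") %in% names(batch)),
            anchor_len >= 1L)
  paired <- if (is.null(partner_batch) || nrow(batch) == 0L) {
    rep(FALSE, nrow(batch))
  } else {
    mate_id(batch$id) %in% partner_batch$id
  }
  if (nrow(batch) == 0L) {
    batch$is_paired_rescue <- logical(0)
    attr(batch, "threshold") <- NA_real_
    return(batch)
  }
  res <- cpp_filter_overlaps(as.integer(batch$overlap),
                             as.integer(anchor_len), paired)
  out <- batch[res$keep, , drop = FALSE]
  out$is_paired_rescue <- paired[res$keep]
  attr(out, "threshold") <- res$threshold
  out
}

#' Mate read id under interleaved pair storage
#'
#' @param id 1-based read ids; reads `2*i - 1` and `2*i` form pair `i`.
#' @return The ids of the mates.
#' @export
mate_id <- function(id) {
  ifelse(id %% 2L == 1L, id + 1L, id - 1L)
}

#' Run the four extension tasks of one indexed pair
#'
#' Executes the full per-pair workflow for pair `pair` of an interleaved
#' index: per iteration and per active task, candidate retrieval from the
#' minhash index, shifted-hamming placement, the pair-aware overlap filter
#' (exchanging candidate batches between partner tasks), MSA construction
#' and refinement, consensus extension, and the mate check for primary
#' tasks; auxiliary tasks stop as soon as their partner stops. The four
#' finished tasks are then combined under all three strict modes.
#'
#' A task's own two reads are excluded from its candidate batches. The mate
#' check scans admissible placements in ascending position and keeps the
#' first hit (placements once scanned are never revisited).
#'
#' @param index A `KmerIndex` over interleaved paired reads.
#' @param pair 1-based pair number (reads `2*pair - 1`, `2*pair`).
#' @param params An [extension_params()] list with resolved
#'   `min_length`/`max_length`.
#' @return A list with per-mode `connected`/`rule`, the result `sequence`
#'   (read 1 strand), `gap_start`/`gap_end` (0-based, half-open),
#'   `out_left`/`out_right`, and the four finished `tasks`.
#' @seealso [extend_pairs()] for all pairs at once.
#' @export
extend_read_pair <- function(index, pair, params) {
  stopifnot(inherits(index, "KmerIndex"))
  params <- resolve_params(params,
                           read_lengths = rep(index$read_length_max, 2L))
  cpp_extend_pair(index$ptr, as.numeric(pair), params)
}
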