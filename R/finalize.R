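#' Extension and finalization parameters
#'
#' Collects every tunable of the per-pair workflow. `min_length` and
#' `max_length` bound the pseudo-long read core (original read to mate);
#' when left `NULL` they are resolved from the insert-size estimate as
#' `max(sum of read lengths, insert_size - 4 * insert_sd)` and
#' `insert_size + 4 * insert_sd`. The mate is accepted at a placement when
#' its hamming distance is at most
#' `ceiling(mate_max_mismatch_frac * mate length)`.
#'
#' @param insert_size,insert_sd Insert-size mean and standard deviation of
#'   the library (the insert includes both read lengths).
#' @param min_length,max_length Pseudo-long read length window; `NULL` =
#'   derive from the insert size.
#' @param max_mismatches,min_overlap_frac Candidate placement constraints
#'   (see [best_alignment()]).
#' @param stepsize,min_coverage,refine_frac,refine_passes MSA extension
#'   controls (see [extend_window()], [refine_msa()]).
#' @param mate_max_mismatch_frac Mate-match tolerance as a fraction of the
#'   mate length (default 0.05).
#' @param strict2_max_hamming Mode 2: maximum hamming distance between the
#'   two tasks' gap sequences (default 0, exact agreement).
#' @param strict1_overlap_frac,strict1_match_frac Mode 1: required overlap
#'   of the partial gap with the filled gap (fraction of the gap size) and
#'   required match fraction inside that overlap.
#' @param merge_min_overlap,merge_max_mismatch_frac Mode 0 merge rule for
#'   two partial extensions (default: at least 40 positions, at most 5%
#'   mismatches).
#' @param outward,outward_cap Optional 5' outward extension from the
#'   auxiliary tasks and its per-side cap (default cap: the insert size).
#' @param max_bucket_size Hash-table bucket cap (see [build_read_index()]).
#' @param threads Accepted for config compatibility; pairs are processed in
#'   a fixed order, so results never depend on it.
#' @return A named list of class `extension_params`.
#' @export
extension_params <- function(insert_size, insert_sd,
                             min_length = NULL, max_length = NULL,
                             max_mismatches = 5L, min_overlap_frac = 0.5,
                             stepsize = 20L, min_coverage = 3L,
                             refine_frac = 0.3, refine_passes = 1L,
                             mate_max_mismatch_frac = 0.05,
                             strict2_max_hamming = 0L,
                             strict1_overlap_frac = 0.5,
                             strict1_match_frac = 0.95,
                             merge_min_overlap = 40L,
                             merge_max_mismatch_frac = 0.05,
                             outward = FALSE, outward_cap = NULL,
                             max_bucket_size = 1000L, threads = 1L) {
  stopifnot(insert_size > 0, insert_sd >= 0, max_mismatches >= 0,
            min_overlap_frac > 0, min_overlap_frac <= 1, stepsize >= 1,
            min_coverage >= 1, refine_frac > 0, refine_frac < 1,
            refine_passes >= 1, mate_max_mismatch_frac >= 0,
            strict2_max_hamming >= 0, strict1_overlap_frac > 0,
            strict1_overlap_frac <= 1, strict1_match_frac > 0,
            strict1_match_frac <= 1, merge_min_overlap >= 1,
            merge_max_mismatch_frac >= 0, threads >= 1)
  if (is.null(outward_cap)) outward_cap <- insert_size
  structure(
    list(insert_size = insert_size, insert_sd = insert_sd,
         min_length = min_length, max_length = max_length,
         max_mismatches = as.integer(max_mismatches),
         min_overlap_frac = min_overlap_frac,
         stepsize = as.integer(stepsize),
         min_coverage = as.integer(min_coverage),
         refine_frac = refine_frac,
         refine_passes = as.integer(refine_passes),
         mate_max_mismatch_frac = mate_max_mismatch_frac,
         strict2_max_hamming = as.integer(strict2_max_hamming),
         strict1_overlap_frac = strict1_overlap_frac,
         strict1_match_frac = strict1_match_frac,
         merge_min_overlap = as.integer(merge_min_overlap),
         merge_max_mismatch_frac = merge_max_mismatch_frac,
         outward = isTRUE(outward), outward_cap = as.integer(outward_cap),
         max_bucket_size = as.integer(max_bucket_size),
         threads = as.integer(threads)),
    class = "extension_params"
  )
}

# Fill min/max length from the insert-size window when not given.
# read_lengths: lengths of the two reads (sum replaces 2 * readlength for
# pairs of unequal length).
resolve_params <- function(params, read_lengths = NULL) {
  stopifnot(inherits(params, "extension_params"))
  if (is.null(params$max_length)) {
    params$max_length <-
      as.integer(round(params$insert_size + 4 * params$insert_sd))
  }
  if (is.null(params$min_length)) {
    if (is.null(read_lengths)) {
      stop("min_length not set and read lengths unknown; pass min_length ",
           "or read_lengths")
    }
    params$min_length <-
      as.integer(max(sum(read_lengths),
                     round(params$insert_size - 4 * params$insert_sd)))
  }
  params$min_length <- as.integer(params$min_length)
  params$max_length <- as.integer(params$max_length)
  if (params$min_length > params$max_length) {
    stop("min_length exceeds max_length")
  }
  params
}

#' Combine four finished extension tasks into a pseudo-long read
#'
#' Applies the three strict modes to the finished tasks of a pair:
#' \describe{
#'   \item{mode 2}{both primary tasks found their mate, the filled gaps have
#'     equal length, and the hamming distance between T1's gap and the
#'     reverse complement of T3's gap is at most `strict2_max_hamming`
#'     (default: exact agreement). T1's contig is the result.}
#'   \item{mode 1}{the mode-2 rule; otherwise, when exactly one primary task
#'     found the mate (gap size s), the other task's partial extension must
#'     overlap the filled gap by at least `strict1_overlap_frac * s`
#'     positions with at least `strict1_match_frac` matches inside the
#'     overlap.}
#'   \item{mode 0}{any mate-finding primary task connects the pair;
#'     otherwise the two partial contigs are merged when a suffix of T1's
#'     contig overlaps a prefix of the reverse complement of T3's by at
#'     least `merge_min_overlap` positions with at most
#'     `merge_max_mismatch_frac` mismatches at a merged length inside the
#'     allowed window (the longest admissible overlap wins).}
#' }
#' All modes report on read 1's strand; original read bases are kept
#' verbatim at both ends. With `outward = TRUE`, bases appended by T4
#' beyond RC1 are reverse-complemented and prepended, and bases appended by
#' T2 beyond RC2 (already on read 1's strand) are appended, each side
#' truncated at `outward_cap`.
#'
#' @param tasks A list of four task lists (order T1, T2, T3, T4), each with
#'   `contig`, `state`, `start_len` and `mate_pos` (0-based, `NA` unless the
#'   mate was found), e.g. the `tasks` element of [extend_read_pair()].
#' @param params An [extension_params()] list with resolved lengths.
#' @return A list with `connected` (logical, modes 0/1/2), `rule`,
#'   `sequence`, `gap_start`/`gap_end`, `out_left`/`out_right`, `tasks`.
#' @export
finalize_pair <- function(tasks, params) {
  stopifnot(is.list(tasks), length(tasks) == 4L)
  contigs <- vapply(tasks, function(t) as_seq_char(t$contig), character(1))
  states <- vapply(tasks, function(t) t$state, character(1))
  start_lens <- vapply(tasks, function(t) {
    if (!is.null(t$start_len)) as.integer(t$start_len)
    else nchar(as_seq_char(t$window %||% t$contig))
  }, integer(1))
  mate_pos <- vapply(tasks, function(t) {
    mp <- t$mate_pos
    if (is.null(mp) || is.na(mp)) NA_integer_ else as.integer(mp)
  }, integer(1))
  params <- resolve_params(params, read_lengths = start_lens[c(1L, 3L)])
  cpp_finalize_pair(contigs, states, start_lens, mate_pos, params)
}

#' Merge two partial directional extensions (strict mode 0)
#'
#' Overlaps a suffix of T1's partial contig with a prefix of the reverse
#' complement of T3's. Admissible overlaps span at least
#' `merge_min_overlap` positions with at most `merge_max_mismatch_frac`
#' mismatches, at a merged length inside `[min_length, max_length]`; the
#' longest admissible overlap is chosen. The mate read's original bases are
#' preserved at the far end of the merged sequence.
#'
#' @param contig1 T1's partial contig (starts with read 1).
#' @param contig3 T3's partial contig (starts with read 2).
#' @param read2_len Length of read 2 (bases preserved at the far end).
#' @param params An [extension_params()] list with resolved lengths.
#' @return A list with `sequence` and `overlap`, or `NULL` when no
#'   admissible overlap exists.
#' @export
merge_partial <- function(contig1, contig3, read2_len, params) {
  params <- resolve_params(params, read_lengths = c(0L, 0L))
  cpp_merge_partial(as_seq_char(contig1), as_seq_char(contig3),
                    as.integer(read2_len), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
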