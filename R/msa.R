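#' Build a column-wise MSA around an anchor window
#'
#' Stacks the anchor and the placed candidate reads into an indel-free MSA:
#' per column, the counts of A/C/G/T. Each candidate contributes its bases
#' (in its aligned orientation) starting at its shift; columns beyond the
#' anchor receive candidate bases only and are the source of extension.
#'
#' @param anchor DNA string or `EncodedSequence`: the current window.
#' @param members A data.frame with columns `sequence` (candidate read, as
#'   stored), `shift` (0-based placement, >= 0) and `orientation`
#'   (`"forward"`/`"revcomp"`), typically from [best_alignment()].
#' @return A `ReadMsa` object: base-count matrix (`counts`, rows A,C,G,T),
#'   per-column `coverage`, `anchor`, `anchor_len`, `ncol`, the kept
#'   `members`, and the current `consensus` string.
#' @examples
#' m <- build_msa("ACGTACGT",
#'                data.frame(sequence = "ACGTACGTAC", shift = 0,
#'                           orientation = "forward"))
#' msa_consensus(m)
#' @export
build_msa <- function(anchor, members = empty_members()) {
  anchor <- as_seq_char(anchor)
  members <- validate_members(members)
  built <- cpp_build_msa(anchor, members$sequence, as.integer(members$shift),
                         members$orientation == "revcomp")
  structure(
    list(anchor = anchor, anchor_len = built$anchor_len, ncol = built$ncol,
         counts = built$counts, coverage = built$coverage,
         members = members, consensus = built$consensus),
    class = "ReadMsa"
  )
}

empty_members <- function() {
  data.frame(sequence = character(), shift = integer(),
             orientation = character(), stringsAsFactors = FALSE)
}

validate_members <- function(members) {
  stopifnot(is.data.frame(members),
            all(c("sequence", "shift", "orientation") %in% names(members)))
  if (nrow(members) > 0) {
    stopifnot(all(members$shift >= 0),
              all(members$orientation %in% c("forward", "revcomp")))
  }
  members
}

#' @export
print.ReadMsa <- function(x, ...) {
  cat(sprintf("ReadMsa: %d columns (%d anchor), %d member reads\n",
              x$ncol, x$anchor_len, nrow(x$members)))
  invisible(x)
}

#' Refine an MSA by its column contents
#'
#' Removes member reads that disagree with the anchor in well-supported
#' ways, the guard against candidates from inexact repeats. For each column
#' covered by the anchor, any non-consensus base `x` carried by at least
#' `refine_frac * coverage` of that column's rows triggers a removal: if the
#' anchor itself carries `x` there, every member *without* `x` in that
#' column is dropped; otherwise every member *with* `x` is dropped. The
#' anchor is never removed; counts are rebuilt after the removals, and the
#' filter can be iterated for `passes` rounds (it stops early at a fixed
#' point; consensus is recomputed each pass).
#'
#' @param msa A `ReadMsa`.
#' @param refine_frac Row-fraction threshold (default 0.3, inclusive).
#' @param passes Maximum number of filter passes (default 1).
#' @return A refined `ReadMsa` containing only the surviving members.
#' @export
refine_msa <- function(msa, refine_frac = 0.3, passes = 1L) {
  stopifnot(inherits(msa, "ReadMsa"), refine_frac > 0, refine_frac < 1,
            passes >= 1L)
  keep <- cpp_refine_msa(msa$anchor, msa$members$sequence,
                         as.integer(msa$members$shift),
                         msa$members$orientation == "revcomp",
                         refine_frac, as.integer(passes))
  build_msa(msa$anchor, msa$members[keep, , drop = FALSE])
}

#' Consensus string of an MSA
#'
#' Per column, the base with the maximal count; ties go to the
#' lexicographically smallest base (A < C < G < T).
#'
#' @param msa A `ReadMsa`.
#' @return A DNA string of length `msa$ncol`.
#' @export
msa_consensus <- function(msa) {
  stopifnot(inherits(msa, "ReadMsa"))
  cpp_consensus_from_counts(msa$counts)
}

#' Extend the anchor window from a refined MSA
#'
#' Let `i` be the first column beyond the anchor. The appended stretch runs
#' from `i` to the largest column `j` with `j - i <= stepsize - 1` such that
#' every column from `i` through `j` has coverage at least `min_coverage`
#' (a contiguous reliable prefix; skipping low-coverage columns would
#' fabricate sequence). The new window drops the same number of bases from
#' its 5' end, so its length is conserved. Extension fails when no column
#' beyond the anchor exists or when column `i` is below `min_coverage`.
#'
#' @param msa A (refined) `ReadMsa` anchored on `window`.
#' @param window The current window; defaults to the MSA's anchor.
#' @param stepsize Maximum bases appended per iteration (default 20).
#' @param min_coverage Minimum column coverage `m` (default 3).
#' @return A list with `status` (`"extended"` or `"failed"`), `appended`
#'   (consensus substring, 1..stepsize bases) and `new_window`.
#' @export
extend_window <- function(msa, window = NULL, stepsize = 20L,
                          min_coverage = 3L) {
  stopifnot(inherits(msa, "ReadMsa"), stepsize >= 1L, min_coverage >= 1L)
  if (is.null(window)) window <- msa$anchor
  window <- as_seq_char(window)
  stopifnot(nchar(window) == msa$anchor_len)
  cpp_extend_window(window, msa$members$sequence,
                    as.integer(msa$members$shift),
                    msa$members$orientation == "revcomp",
                    as.integer(stepsize), as.integer(min_coverage))
}
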