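#' Best indel-free placement of a candidate read on an anchor window
#'
#' Evaluates every shift in `[0, nchar(anchor) - 1]` for both orientations of
#' the candidate and returns the admissible placement with the fewest
#' mismatches. A placement is admissible when its overlap is at least
#' `min_overlap_frac` of the candidate length and its mismatch count is at
#' most `max_mismatches`. The candidate is never placed left of the anchor
#' (shift >= 0): extension only proceeds towards the 3' end, so a
#' candidate's first base must fall inside the overlap. Candidates longer
#' than the anchor are allowed; the overlap is clipped at the anchor end and
#' the bases beyond it later feed the MSA columns past the window.
#'
#' Ties are broken deterministically: fewer mismatches, then larger overlap,
#' then smaller shift, then forward orientation.
#'
#' @param anchor,candidate DNA strings or `EncodedSequence` objects.
#' @param max_mismatches Maximum mismatches in the overlap (default 5).
#' @param min_overlap_frac Minimum overlap as a fraction of the candidate
#'   length (default 0.5).
#' @return A list with `shift` (0-based), `overlap`, `mismatches` and
#'   `orientation` (`"forward"` or `"revcomp"`), or `NULL` when no
#'   admissible placement exists.
#' @examples
#' best_alignment("AAAACCCC", "CCCCGGGG")  # shift 4, overlap 4, 0 mismatches
#' @export
best_alignment <- function(anchor, candidate, max_mismatches = 5L,
                           min_overlap_frac = 0.5) {
  anchor <- as_seq_char(anchor)
  candidate <- as_seq_char(candidate)
  stopifnot(nchar(anchor) >= 1L, nchar(candidate) >= 1L,
            max_mismatches >= 0L,
            min_overlap_frac > 0, min_overlap_frac <= 1)
  cpp_best_alignment(anchor, candidate, as.integer(max_mismatches),
                     min_overlap_frac)
}
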