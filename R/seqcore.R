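#' Encode a DNA sequence into 2-bit packed form
#'
#' Sequences are stored with two bits per base (A=0, C=1, G=2, T=3), four
#' bases per byte. IUPAC ambiguity codes are deterministically replaced by
#' the lexicographically smallest compatible base (N, R, W, M, D, H, V to A;
#' Y, S, B to C; K to G; U is read as T). Parsing is case-insensitive;
#' decoding always yields upper-case ACGT.
#'
#' @param text A single DNA string over the IUPAC alphabet (non-empty).
#' @return An `EncodedSequence`: a list with elements `data` (packed raw
#'   vector) and `length` (number of bases).
#' @examples
#' s <- encode_sequence("GATTACA")
#' decode_sequence(s)
#' @seealso [decode_sequence()], [reverse_complement()], [hamming_distance()]
#' @export
encode_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  codes <- cpp_encode(text)
  structure(list(data = cpp_pack(codes), length = length(codes)),
            class = "EncodedSequence")
}

#' Decode a 2-bit packed sequence back to a DNA string
#'
#' @param x An `EncodedSequence` created by [encode_sequence()].
#' @return A character scalar over ACGT.
#' @export
decode_sequence <- function(x) {
  stopifnot(inherits(x, "EncodedSequence"))
  cpp_decode(cpp_unpack(x$data, x$length))
}

#' @export
length.EncodedSequence <- function(x) x$length

#' @export
as.character.EncodedSequence <- function(x, ...) decode_sequence(x)

#' @export
print.EncodedSequence <- function(x, ...) {
  s <- decode_sequence(x)
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("EncodedSequence of %d bases: %s\n", x$length, shown))
  invisible(x)
}

# Coerce character / EncodedSequence input to a plain character scalar.
as_seq_char <- function(x) {
  if (inherits(x, "EncodedSequence")) return(decode_sequence(x))
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x
}

#' Reverse complement
#'
#' Watson-Crick reverse complement. Accepts a character vector (element-wise)
#' or an `EncodedSequence` (returned as an `EncodedSequence`).
#'
#' @param x Character vector of DNA strings, or an `EncodedSequence`.
#' @return Same type as the input.
#' @examples
#' reverse_complement("AAC")
#' @export
reverse_complement <- function(x) {
  if (inherits(x, "EncodedSequence")) {
    return(encode_sequence(cpp_revcomp(decode_sequence(x))))
  }
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Hamming distance between two equal-length sequences
#'
#' Number of mismatching positions. Ambiguity codes are replaced by the
#' deterministic rule of [encode_sequence()] before comparison.
#'
#' @param a,b DNA strings or `EncodedSequence` objects of equal length.
#' @return Integer mismatch count.
#' @examples
#' hamming_distance("AAAA", "AATA")
#' @export
hamming_distance <- function(a, b) {
  a <- as_seq_char(a)
  b <- as_seq_char(b)
  if (nchar(a) != nchar(b)) {
    stop("hamming_distance() requires equal-length sequences (",
         nchar(a), " vs ", nchar(b), ")")
  }
  cpp_hamming(a, b)
}
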