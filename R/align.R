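#' Longest local alignment between two sequences
#'
#' Length, in aligned columns, of the best-scoring local alignment between
#' `a` and `b`, considering `b` in both forward and reverse-complement
#' orientation. Scoring is BLAST-like: match +1, mismatch -3, gap open/extend
#' 5/2 (a gap of length k costs 5 + 2k). Among score-optimal alignments the
#' longest is reported. When `a` and `b` are the same sequence, self-hits on
#' the main diagonal are excluded so the value reflects internal similarity
#' only.
#'
#' The panel designer rejects sequence pairs whose value exceeds
#' `max_cross_alignment` (default 16 bp), keeping spike-ins mutually
#' dissimilar and unambiguous to assign.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_ext alignment scoring parameters.
#' @return integer: aligned columns of the best local alignment over both
#'   orientations.
#' @export
#' @examples
#' cross_similarity("ACGTACGTACGTACGTACGTAAAA", "ACGTACGTACGTACGTACGT")
cross_similarity <- function(a, b, match = 1, mismatch = -3,
                             gap_open = 5, gap_ext = 2) {
  a <- assert_dna(a)
  b <- assert_dna(b)
  self <- identical(a, b)
  fwd <- .local_align_cpp(a, b, match, mismatch, gap_open, gap_ext,
                          self_exclude = self)
  rev <- .local_align_cpp(a, revcomp(b), match, mismatch, gap_open, gap_ext,
                          self_exclude = FALSE)
  as.integer(max(fwd$length, rev$length))
}

#' Longest exact substring shared by two sequences
#'
#' Length of the longest substring of `a` that also occurs in `b`, forward or
#' reverse-complemented. A parameter-free companion to [cross_similarity()]:
#' the panel screen enforces both, so no pair of designed sequences shares a
#' long exact word even where gapped alignments score poorly.
#'
#' @param a,b DNA strings.
#' @return integer length (0 if not even a single base is shared).
#' @export
longest_shared_substring <- function(a, b) {
  a <- assert_dna(a)
  b <- assert_dna(b)
  brc <- revcomp(b)
  shared_at <- function(k) {
    ka <- kmers_of(a, k)
    length(ka) && any(ka %in% kmers_of(b, k) | ka %in% kmers_of(brc, k))
  }
  largest_true(shared_at, 1L, min(nchar(a), nchar(b)))
}
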