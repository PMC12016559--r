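#' Full-matrix Gotoh global alignment (trusted reference)
#'
#' Exact affine-gap global alignment over the complete score matrix, written
#' as a plain absolute-score sweep with no code shared with the banded
#' striped kernel. Tie-breaking matches the aligner (diagonal, then
#' reference gap, then query gap; gap extension beats re-opening), so
#' tracebacks are deterministic.
#'
#' @param query,reference nucleotide strings (A/C/G/T/N, case-insensitive;
#'   other IUPAC codes fold to N).
#' @param scheme a [scoring_scheme()].
#' @param want_cigar also compute the optimal path (needs the full pointer
#'   matrix; disable for long sequences).
#' @return A list with `score` and `cigar` (`NULL` when `want_cigar` is
#'   `FALSE`).
#' @examples
#' gotoh_global("ACGT", "ACGT")$score  # 8
#' gotoh_global("ACGT", "AGT")$score   # 0
#' @export
gotoh_global <- function(query, reference, scheme = scoring_scheme(),
                         want_cigar = TRUE) {
  .check_scheme(scheme)
  q <- normalize_seq(query, "query")
  r <- normalize_seq(reference, "reference")
  res <- .gotoh_global_cpp(q, r, scheme$match, scheme$mismatch,
                           scheme$gap_open_ext, scheme$gap_ext, want_cigar)
  list(score = res$score, cigar = res$cigar)
}

#' Full-matrix Smith-Waterman local alignment (trusted reference)
#'
#' Standard local alignment: scores are floored at zero and the best-scoring
#' cell is traced back to the nearest zero. Test oracle only.
#'
#' @inheritParams gotoh_global
#' @return A list with `score`, `cigar` and 0-based half-open `query_range`
#'   and `ref_range` (empty alignment when the score is 0).
#' @export
sw_local <- function(query, reference, scheme = scoring_scheme()) {
  .check_scheme(scheme)
  q <- normalize_seq(query, "query")
  r <- normalize_seq(reference, "reference")
  res <- .sw_local_cpp(q, r, scheme$match, scheme$mismatch,
                       scheme$gap_open_ext, scheme$gap_ext)
  list(score = res$score, cigar = res$cigar,
       query_range = res$query_range, ref_range = res$ref_range)
}

#' Wagner-Fischer edit distance (trusted reference)
#'
#' Exact unit-cost Levenshtein distance by the textbook row-sweep DP; the
#' comparator for the bit-vector edit engine.
#'
#' @inheritParams gotoh_global
#' @return Integer distance.
#' @examples
#' wagner_fischer("ACGT", "AGT")  # 1
#' @export
wagner_fischer <- function(query, reference) {
  q <- normalize_seq(query, "query")
  r <- normalize_seq(reference, "reference")
  as.integer(.wagner_fischer_cpp(q, r))
}
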