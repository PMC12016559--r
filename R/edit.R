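#' Bit-vector edit distance
#'
#' Unit-cost (Levenshtein) global alignment distance computed with a
#' Myers-style block bit-vector engine over 64-bit words. With
#' `limit = NULL` ("whole" mode) the exact distance is returned. With a
#' finite `limit` k ("limit" mode) the computation is restricted to the
#' Ukkonen band determined by k -- blocks that provably cannot stay within k
#' are never computed -- and the result is the exact distance when it is
#' at most k, or `exceeded = TRUE` otherwise.
#'
#' N mismatches everything, including another N.
#'
#' @param query,reference nucleotide strings (A/C/G/T/N, case-insensitive;
#'   other IUPAC codes fold to N).
#' @param limit maximum distance k (>= 0), or `NULL` for the whole mode.
#' @param want_cigar also compute an optimal unit-cost path (stores the
#'   per-column block states and walks them back).
#' @return An object of class `bandstripe_edit`: a list with `distance`
#'   (integer, `NA` when exceeded), `exceeded` (logical), `cigar` (or
#'   `NULL`), and `cells` (DP cells examined, for work accounting).
#' @examples
#' edit_distance("ACGT", "AGT")$distance            # 1
#' edit_distance("ACGT", "TTTT", limit = 1)$exceeded  # TRUE
#' @export
edit_distance <- function(query, reference, limit = NULL, want_cigar = FALSE) {
  q <- normalize_seq(query, "query")
  r <- normalize_seq(reference, "reference")
  if (!is.null(limit)) {
    if (!.is_count(limit) || limit < 0)
      stop("limit must be a single integer >= 0, or NULL")
  }
  res <- .edit_distance_cpp(q, r, if (is.null(limit)) -1 else as.double(limit),
                            want_cigar)
  structure(list(
    distance = if (is.null(res$distance)) NA_integer_ else as.integer(res$distance),
    exceeded = res$exceeded,
    cigar = res$cigar,
    cells = res$cells), class = "bandstripe_edit")
}

#' @export
print.bandstripe_edit <- function(x, ...) {
  if (x$exceeded) cat("<bandstripe_edit> distance EXCEEDED limit\n")
  else cat(sprintf("<bandstripe_edit> distance %d\n", x$distance))
  if (!is.null(x$cigar)) cat("  cigar:", x$cigar, "\n")
  invisible(x)
}

#' Edit-distance traceback
#'
#' Returns an optimal unit-cost alignment path for a pair whose distance is
#' already known; the number of `X` + `I` + `D` columns equals the distance
#' and the path consumes both sequences fully.
#'
#' @inheritParams edit_distance
#' @param distance the distance previously returned by [edit_distance()]
#'   for the same pair (checked).
#' @return A CIGAR string over `=`, `X`, `I`, `D`.
#' @export
edit_cigar <- function(query, reference, distance) {
  if (!.is_count(distance) || distance < 0)
    stop("distance must be a single integer >= 0")
  res <- edit_distance(query, reference, limit = NULL, want_cigar = TRUE)
  if (res$distance != distance)
    stop(sprintf("supplied distance %d does not match the computed distance %d",
                 as.integer(distance), res$distance))
  res$cigar
}
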