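#' Affine-gap scoring scheme
#'
#' Bundles the four alignment score parameters: match reward, mismatch
#' penalty, gap-open penalty and gap-extension penalty. Penalties are stored
#' as negative integers. The combined open-plus-extend penalty
#' `gap_open_ext = gap_open + gap_ext` is the cost of the first base of a
#' gap; each further base costs `gap_ext`.
#'
#' The defaults (2, -4, -4, -2) give `gap_open_ext = -6`.
#'
#' @param match match score, a positive integer.
#' @param mismatch mismatch score, a negative integer.
#' @param gap_open gap-open penalty, a non-positive integer.
#' @param gap_ext gap-extension penalty, a negative integer.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 1, mismatch = -1, gap_open = -2, gap_ext = -1)
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                           gap_ext = -2L) {
  vals <- c(match = match, mismatch = mismatch, gap_open = gap_open,
            gap_ext = gap_ext)
  if (any(!vapply(vals, .is_count, logical(1))))
    stop("all scoring parameters must be single integer values")
  if (match <= 0) stop("match score must be positive")
  if (mismatch >= 0) stop("mismatch score must be negative")
  if (gap_ext >= 0) stop("gap extension penalty must be negative")
  if (gap_open > 0) stop("gap open penalty must be non-positive")
  goe <- gap_open + gap_ext
  if (goe > gap_ext)
    stop("opening a gap must not be cheaper than extending one (gap_open + gap_ext <= gap_ext)")
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext),
         gap_open_ext = as.integer(goe)),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match %d, mismatch %d, gap open %d, gap ext %d (open+ext %d)\n",
    x$match, x$mismatch, x$gap_open, x$gap_ext, x$gap_open_ext))
  invisible(x)
}

.check_scheme <- function(s) {
  if (!inherits(s, "scoring_scheme"))
    stop("expected a 'scoring_scheme' object (see scoring_scheme())")
  s
}

#' Per-base substitution score
#'
#' Returns the match score when the two symbols are equal and neither is N,
#' and the mismatch score otherwise; N never matches, not even another N.
#' Vectorized over pairs of symbols (recycled to a common length).
#'
#' @param a,b nucleotide symbols from A/C/G/T/N (case-insensitive).
#' @param scheme a [scoring_scheme()].
#' @return Integer vector of substitution scores.
#' @examples
#' substitution_score("A", "A", scoring_scheme())  # 2
#' substitution_score("A", "C", scoring_scheme())  # -4
#' substitution_score("N", "N", scoring_scheme())  # -4
#' @export
substitution_score <- function(a, b, scheme = scoring_scheme()) {
  .check_scheme(scheme)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  bad <- c(a, b)[!(c(a, b) %in% c("A", "C", "G", "T", "N"))]
  if (length(bad) > 0)
    stop(sprintf("invalid nucleotide symbol '%s' (expected A/C/G/T/N)", bad[1]))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ifelse(a == b & a != "N", scheme$match, scheme$mismatch)
}

#' Cost of a contiguous gap
#'
#' The affine cost of a gap of the given length:
#' `gap_open_ext + (length - 1) * gap_ext`. Vectorized over lengths.
#'
#' @param length gap length(s), positive integers.
#' @param scheme a [scoring_scheme()].
#' @return Integer vector of (negative) gap costs.
#' @examples
#' gap_cost(1, scoring_scheme())  # -6
#' gap_cost(3, scoring_scheme())  # -10
#' @export
gap_cost <- function(length, scheme = scoring_scheme()) {
  .check_scheme(scheme)
  if (length(length) == 0 || any(!is.finite(length)) ||
      any(length < 1) || any(length != floor(length)))
    stop("gap length must consist of integers >= 1")
  as.integer(scheme$gap_open_ext + (length - 1) * scheme$gap_ext)
}
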